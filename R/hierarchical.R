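#' Bonferroni-adjusted set-level p-value
#'
#' For a set with m subsets and raw subset p-values P_j, the set-level
#' adjusted p-value is `min_j(m * P_j)`, capped at 1. The set is the union
#' of its subsets, so evidence against any one subset is evidence against
#' the set, and the Bonferroni factor m accounts for looking at all of them.
#'
#' @param subset_pvalues numeric vector of raw subset p-values in (0, 1].
#' @return a single number in (0, 1].
#' @export
bonferroni_set_adjusted_p <- function(subset_pvalues) {
  if (length(subset_pvalues) < 1L) stop("empty p-value list")
  if (any(!is.finite(subset_pvalues)) || any(subset_pvalues <= 0) ||
      any(subset_pvalues > 1))
    stop("p-values must lie in (0, 1]")
  min(1, length(subset_pvalues) * min(subset_pvalues))
}

check_pvalue_families <- function(pvalues_by_set, alpha) {
  if (!is.list(pvalues_by_set) || length(pvalues_by_set) < 1L)
    stop("`pvalues_by_set` must be a non-empty list (one element per set)")
  if (is.null(names(pvalues_by_set)))
    names(pvalues_by_set) <- paste0("set", seq_along(pvalues_by_set))
  for (p in pvalues_by_set)
    if (length(p) < 1L || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
      stop("every set needs >= 1 raw p-value, all in (0, 1]")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1)
    stop("`alpha` must lie in [0, 1)")
  pvalues_by_set
}

report_skeleton <- function(pvalues_by_set) {
  K <- length(pvalues_by_set)
  m <- lengths(pvalues_by_set)
  subset_names <- lapply(pvalues_by_set, function(p) {
    if (is.null(names(p))) paste0("subset", seq_along(p)) else names(p)
  })
  list(K = K, m = m,
       set = rep(names(pvalues_by_set), times = m),
       subset = unlist(subset_names, use.names = FALSE),
       p = unlist(pvalues_by_set, use.names = FALSE),
       adj = vapply(pvalues_by_set, bonferroni_set_adjusted_p, numeric(1)))
}

#' Two-level Bonferroni test of sets and subsets (FWER control)
#'
#' Implements the hierarchical decision rule: a set S_k is declared
#' significant when its Bonferroni-adjusted p-value P*_k = min_j(m_k P_kj)
#' is below `alpha/K`; a subset S_kj is declared significant when its raw
#' p-value is below `alpha/(K * m_k)`. The two rules coincide at the set
#' level (a set is significant iff one of its subsets is), and the
#' procedure strongly controls the overall family-wise error rate at
#' `alpha` under arbitrary dependence among the test statistics.
#'
#' @param pvalues_by_set named list, one numeric vector of raw subset
#'   p-values per set (names of the vectors name the subsets).
#' @param alpha overall FWER level in (0, 1); `alpha = 0` rejects nothing.
#' @return list of class `hier_test_report` with `subsets` (data.frame:
#'   set, subset, p, subset_threshold, subset_significant, set_significant),
#'   `sets` (data.frame: set, m, adjusted_p, overall_adjusted_p, threshold,
#'   significant), `alpha`, `K`, `procedure = "bonferroni"`.
#' @export
hierarchical_fwer_test <- function(pvalues_by_set, alpha = 0.05) {
  pvalues_by_set <- check_pvalue_families(pvalues_by_set, alpha)
  sk <- report_skeleton(pvalues_by_set)
  set_thresh <- alpha / sk$K
  set_sig <- sk$adj < set_thresh            # strict: "is less than"
  sub_thresh <- rep(alpha / (sk$K * sk$m), times = sk$m)
  sub_sig <- sk$p < sub_thresh
  sets <- data.frame(set = names(pvalues_by_set), m = as.integer(sk$m),
                     adjusted_p = sk$adj,
                     overall_adjusted_p = pmin(1, sk$K * sk$adj),
                     threshold = set_thresh, significant = set_sig,
                     row.names = NULL)
  subsets <- data.frame(set = sk$set, subset = sk$subset, p = sk$p,
                        subset_threshold = sub_thresh,
                        subset_significant = sub_sig,
                        set_significant = rep(set_sig, times = sk$m),
                        row.names = NULL)
  structure(list(subsets = subsets, sets = sets, alpha = alpha, K = sk$K,
                 procedure = "bonferroni"),
            class = "hier_test_report")
}

#' Two-stage BH variant selecting sets by FDR
#'
#' Replaces the set-level Bonferroni rule with the Benjamini-Hochberg
#' step-up procedure applied at level `alpha` to the K set-level adjusted
#' p-values P*_k (selection uses `<=` per the standard step-up definition).
#' Within each of the R selected sets, a subset is flagged when its raw
#' p-value satisfies `P_kj <= R * alpha / (K * m_k)` — the two-stage
#' construction that scales the subset threshold by the number of selected
#' sets. The report labels this rule `"fdr-two-stage"`.
#'
#' @inheritParams hierarchical_fwer_test
#' @return list of class `hier_test_report`, as for
#'   [hierarchical_fwer_test()] but with `procedure = "fdr-two-stage"` and
#'   `n_selected` (the number R of BH-selected sets).
#' @export
hierarchical_fdr_test <- function(pvalues_by_set, alpha = 0.05) {
  pvalues_by_set <- check_pvalue_families(pvalues_by_set, alpha)
  sk <- report_skeleton(pvalues_by_set)
  K <- sk$K
  # BH step-up on the K adjusted p-values
  ord <- order(sk$adj)
  ok <- sk$adj[ord] <= (seq_len(K) * alpha / K)
  R <- if (any(ok)) max(which(ok)) else 0L
  set_sig <- logical(K)
  if (R > 0) set_sig[ord[seq_len(R)]] <- TRUE
  sub_thresh <- rep(R * alpha / (K * sk$m), times = sk$m)
  sub_sig <- rep(set_sig, times = sk$m) & (sk$p <= sub_thresh)
  sets <- data.frame(set = names(pvalues_by_set), m = as.integer(sk$m),
                     adjusted_p = sk$adj,
                     overall_adjusted_p = pmin(1, K * sk$adj),
                     threshold = R * alpha / K, significant = set_sig,
                     row.names = NULL)
  subsets <- data.frame(set = sk$set, subset = sk$subset, p = sk$p,
                        subset_threshold = sub_thresh,
                        subset_significant = sub_sig,
                        set_significant = rep(set_sig, times = sk$m),
                        row.names = NULL)
  structure(list(subsets = subsets, sets = sets, alpha = alpha, K = K,
                 procedure = "fdr-two-stage", n_selected = R),
            class = "hier_test_report")
}

#' @export
print.hier_test_report <- function(x, ...) {
  cat("hierarchical test report (", x$procedure, "), K = ", x$K,
      " sets, alpha = ", x$alpha, "\n", sep = "")
  cat("  significant sets:   ", sum(x$sets$significant), "/", x$K, "\n")
  cat("  significant subsets:", sum(x$subsets$subset_significant), "/",
      nrow(x$subsets), "\n")
  invisible(x)
}
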