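#' Full hierarchical gene set/subset analysis
#'
#' Runs the complete procedure on one study: (1) compute the observed
#' subset statistics, (2) simulate their joint null distribution by the
#' residual bootstrap, (3) convert to raw bootstrap p-values, and (4) apply
#' the two-level Bonferroni rule (or the BH two-stage variant) to flag
#' significant sets and subsets.
#'
#' @param study an [expression_study()]; paired mode requires
#'   `statistic = "paired"`.
#' @param hierarchy a [gene_set_hierarchy()].
#' @param alpha overall error level (default 0.05).
#' @param B bootstrap replicates (default 5000). The smallest attainable
#'   p-value is `1/(B+1)`; choose B so that `1/(B+1)` is below
#'   `alpha/(K * max(m_k))` or deep subset thresholds are unreachable.
#' @param seed integer RNG seed (reproducible end to end).
#' @param procedure `"bonferroni"` (FWER control, default) or `"bh"`
#'   (two-stage FDR variant).
#' @param statistic `"diag"` (default), `"full"`, or `"paired"`.
#' @param cond_ceiling condition-number ceiling for `statistic = "full"`.
#' @return list of class `gsa_result`: the `hier_test_report` fields plus a
#'   `statistic` column (observed subset statistics) in `$subsets`, and
#'   `B`, `seed`, `statistic_kind`.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(10 * 12), 10, 12,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
#' m[1:3, 7:12] <- m[1:3, 7:12] + 3   # strong signal in g1-g3
#' study <- expression_study(m, group = rep(1:2, each = 6))
#' h <- gene_set_hierarchy(list(
#'   A = list(hit = paste0("g", 1:3), null = paste0("g", 4:6)),
#'   B = list(null = paste0("g", 7:10))))
#' res <- gsa_test(study, h, B = 500, seed = 42)
#' res$subsets
#' @export
gsa_test <- function(study, hierarchy, alpha = 0.05, B = 5000, seed = 1,
                     procedure = c("bonferroni", "bh"),
                     statistic = c("diag", "full", "paired"),
                     cond_ceiling = 1e12) {
  procedure <- match.arg(procedure)
  statistic <- match.arg(statistic)
  stopifnot(inherits(study, "expression_study"),
            inherits(hierarchy, "gene_set_hierarchy"))
  flat <- flatten_hierarchy(hierarchy, study$gene_ids)

  obs <- if (statistic == "paired") {
    d <- paired_differences(study)
    vapply(flat$index, function(i) paired_diag_t2(d, i), numeric(1))
  } else {
    mom <- compute_group_moments(study,
                                 with_full_cov = statistic == "full")
    if (statistic == "diag")
      vapply(flat$index, function(i) diag_t2(mom, i), numeric(1))
    else
      vapply(flat$index, function(i)
        full_t2(mom, i, cond_ceiling = cond_ceiling), numeric(1))
  }

  nd <- bootstrap_null_statistics(study, hierarchy, B = B, seed = seed,
                                  statistic = statistic,
                                  cond_ceiling = cond_ceiling)
  p <- vapply(seq_along(obs), function(s)
    bootstrap_pvalue(obs[s], nd$stats[s, ]), numeric(1))

  by_set <- split(stats::setNames(p, flat$subset),
                  factor(flat$set, levels = names(hierarchy$sets)))
  report <- if (procedure == "bonferroni")
    hierarchical_fwer_test(by_set, alpha = alpha)
  else
    hierarchical_fdr_test(by_set, alpha = alpha)

  report$subsets <- cbind(report$subsets[, c("set", "subset")],
                          statistic = obs,
                          report$subsets[, setdiff(names(report$subsets),
                                                   c("set", "subset"))])
  report$B <- nd$B
  report$seed <- nd$seed
  report$statistic_kind <- statistic
  class(report) <- c("gsa_result", class(report))
  report
}

#' @export
print.gsa_result <- function(x, ...) {
  cat("gene set/subset analysis (", x$statistic_kind, " T2, ",
      x$procedure, ", B = ", x$B, ", seed = ", x$seed, ")\n", sep = "")
  NextMethod()
}
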