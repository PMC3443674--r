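#' Residual-bootstrap null population of a two-group study
#'
#' Replaces every sample by the weighted grand mean plus that sample's
#' within-group deviation: sample j of group i becomes
#' \eqn{\bar{\bar X} + (X_{ij} - \bar X_i)}. Both groups of the transformed
#' study then have sample mean exactly the grand mean — the null of equal
#' means holds by construction — while each group's own variances and
#' dependence structure are untouched. Resampling subjects with replacement
#' from this population simulates the null distribution of the subset
#' statistics under heteroscedasticity; pooling the raw groups (the standard
#' bootstrap) would not honour a between-group difference in covariance
#' structure.
#'
#' @param study an [expression_study()] in two-group mode.
#' @return a new `expression_study` with the transformed matrix and the same
#'   design.
#' @export
build_null_population <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (study$mode != "two_group") stop("`study` must be a two-group design")
  g1 <- study$group == 1L
  m1 <- rowMeans(study$matrix[, g1, drop = FALSE])
  m2 <- rowMeans(study$matrix[, !g1, drop = FALSE])
  n1 <- sum(g1); n2 <- sum(!g1)
  grand <- (n1 * m1 + n2 * m2) / (n1 + n2)
  out <- study
  out$matrix[, g1] <- study$matrix[, g1, drop = FALSE] - m1 + grand
  out$matrix[, !g1] <- study$matrix[, !g1, drop = FALSE] - m2 + grand
  out
}

#' Bootstrap null distribution of subset statistics
#'
#' Simulates the joint null distribution of the chosen statistic over every
#' subset of a hierarchy. For each of B replicates, subjects are drawn with
#' replacement within each group from the residual-bootstrap null population
#' (see [build_null_population()]), and the statistic is evaluated for every
#' subset on that same resample — sharing resamples across subsets leaves
#' each marginal null distribution unchanged while costing O(B) draws.
#'
#' In paired mode the per-pair difference vectors are centred at their mean
#' and whole centred difference columns are resampled with replacement.
#'
#' Degenerate resamples (a gene constant within a resampled group) are
#' handled by flooring bootstrap variances at `1e-12` times the largest
#' observed per-gene variance; observed-data statistics are never floored.
#'
#' @param study an [expression_study()] (two-group mode, or paired mode for
#'   `statistic = "paired"`).
#' @param hierarchy a [gene_set_hierarchy()]; all gene ids must resolve
#'   against the study.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed; identical inputs and seed reproduce the null
#'   distribution bit for bit.
#' @param statistic `"diag"` (default), `"full"`, or `"paired"`.
#' @param cond_ceiling condition-number ceiling passed through for
#'   `statistic = "full"` observed values.
#' @return list of class `null_distribution`: `stats` (subsets x B matrix,
#'   rows named `set|subset`), `set`, `subset`, `B`, `seed`, `statistic`.
#' @export
bootstrap_null_statistics <- function(study, hierarchy, B, seed,
                                      statistic = c("diag", "full",
                                                    "paired"),
                                      cond_ceiling = 1e12) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(study, "expression_study"),
            inherits(hierarchy, "gene_set_hierarchy"))
  if (!is.numeric(B) || length(B) != 1L || B < 1)
    stop("`B` must be a positive integer")
  B <- as.integer(B)
  flat <- flatten_hierarchy(hierarchy, study$gene_ids)
  n_subsets <- length(flat$index)
  if (as.double(B) * n_subsets > 5e8)
    stop("B * number of subsets exceeds the in-memory budget; reduce B")

  if (statistic == "paired") {
    if (study$mode != "paired")
      stop("`statistic = \"paired\"` needs a paired study")
    d <- paired_differences(study)
    d0 <- d - rowMeans(d)          # centred: zero-mean differences hold
    n <- ncol(d0)
    floor_v <- 1e-12 * max(rowSums((d - rowMeans(d))^2) / (n - 1))
    set.seed(seed)
    idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    stats <- cpp_boot_paired(d0, flat$index, idx, floor_v)
  } else {
    if (study$mode != "two_group")
      stop("two-group statistics need a two-group study")
    null_pop <- build_null_population(study)
    x1 <- group_columns(null_pop, 1L)
    x2 <- group_columns(null_pop, 2L)
    n1 <- ncol(x1); n2 <- ncol(x2)
    set.seed(seed)
    idx1 <- matrix(sample.int(n1, n1 * B, replace = TRUE), n1, B)
    idx2 <- matrix(sample.int(n2, n2 * B, replace = TRUE), n2, B)
    if (statistic == "diag") {
      v1 <- rowSums((x1 - rowMeans(x1))^2) / (n1 - 1)
      v2 <- rowSums((x2 - rowMeans(x2))^2) / (n2 - 1)
      floor_v <- 1e-12 * max(v1, v2)
      stats <- cpp_boot_diag(x1, x2, flat$index, idx1, idx2, floor_v)
    } else {
      sizes <- lengths(flat$index)
      if (any(sizes >= min(n1, n2)))
        stop("full-covariance statistic needs the per-group sample size ",
             "to exceed every subset size (largest subset: ", max(sizes),
             " genes, smallest group: ", min(n1, n2), " samples)")
      stats <- cpp_boot_full(x1, x2, flat$index, idx1, idx2)
    }
  }
  rownames(stats) <- paste(flat$set, flat$subset, sep = "|")
  structure(list(stats = stats, set = flat$set, subset = flat$subset,
                 B = B, seed = as.integer(seed), statistic = statistic),
            class = "null_distribution")
}

#' Bootstrap p-value of an observed statistic
#'
#' Returns `(1 + #\{b : T*_b >= observed\}) / (B + 1)`: the add-one
#' convention keeps every p-value strictly positive and the test valid
#' (the observed statistic is ranked among B + 1 exchangeable values under
#' the null). The smallest attainable p-value is `1/(B + 1)`.
#'
#' @param observed observed statistic (finite scalar).
#' @param null_stats numeric vector of B bootstrap statistics.
#' @return a number in `(0, 1]`.
#' @export
bootstrap_pvalue <- function(observed, null_stats) {
  if (length(null_stats) < 1L) stop("`null_stats` must be non-empty")
  if (!is.finite(observed)) stop("`observed` must be finite")
  (1 + sum(null_stats >= observed)) / (length(null_stats) + 1)
}
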