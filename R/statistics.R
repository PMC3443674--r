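#' Per-group first and second moments of a two-group study
#'
#' Computes the two sample mean vectors, the per-gene sample variances
#' (denominator n_i - 1), optionally the full sample covariance matrices,
#' and the weighted grand mean (n1*mean1 + n2*mean2)/(n1+n2) that anchors
#' the residual bootstrap null population.
#'
#' A gene whose variance is zero in both groups makes the diagonal statistic
#' undefined, so such genes are rejected here by name rather than silently
#' floored.
#'
#' @param study an [expression_study()] in two-group mode.
#' @param with_full_cov also compute the full covariance matrices `cov_1`,
#'   `cov_2` (needed by [full_t2()]). Default `FALSE`.
#' @return list of class `group_moments`: `mean_1`, `mean_2`, `diagvar_1`,
#'   `diagvar_2`, `n_1`, `n_2`, `grand_mean`, `gene_ids`, and `cov_1`/`cov_2`
#'   when requested.
#' @export
compute_group_moments <- function(study, with_full_cov = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  if (study$mode != "two_group")
    stop("`study` must be a two-group design")
  x1 <- group_columns(study, 1L)
  x2 <- group_columns(study, 2L)
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  dead <- which(v1 == 0 & v2 == 0)
  if (length(dead) > 0)
    stop("gene(s) with zero variance in both groups (statistic undefined): ",
         paste(utils::head(study$gene_ids[dead], 10), collapse = ", "))
  out <- list(mean_1 = m1, mean_2 = m2,
              diagvar_1 = v1, diagvar_2 = v2,
              n_1 = n1, n_2 = n2,
              grand_mean = (n1 * m1 + n2 * m2) / (n1 + n2),
              gene_ids = study$gene_ids)
  if (isTRUE(with_full_cov)) {
    out$cov_1 <- stats::cov(t(x1))
    out$cov_2 <- stats::cov(t(x2))
  }
  class(out) <- "group_moments"
  out
}

# Map a gene selection (character ids or integer indices) onto moment
# vectors; shared by the statistic functions.
resolve_genes <- function(moments, genes) {
  if (length(genes) == 0) stop("empty gene list")
  if (is.character(genes)) {
    idx <- match(genes, moments$gene_ids)
    if (anyNA(idx))
      stop("unknown gene id(s): ",
           paste(genes[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(genes)
    if (any(idx < 1L | idx > length(moments$gene_ids)))
      stop("gene index out of range")
  }
  idx
}

#' Diagonal Hotelling-type T2 statistic for a gene subset
#'
#' The two-sample statistic
#' \deqn{T^2_{diag} = (\bar x_1 - \bar x_2)' \{Diag(S_1)/n_1 +
#'   Diag(S_2)/n_2\}^{-1} (\bar x_1 - \bar x_2),}
#' i.e. the sum over the subset's genes of squared Welch t statistics.
#' Unlike the classical Hotelling T2 it needs no matrix inversion, remains
#' defined when genes outnumber samples, and allows the two groups unequal
#' variances.
#'
#' @param moments a `group_moments` object from [compute_group_moments()].
#' @param genes gene identifiers (character) or indices (integer) selecting
#'   the subset; must be non-empty.
#' @return a single non-negative number.
#' @seealso [full_t2()] for the full-covariance analogue, [paired_diag_t2()]
#'   for paired designs.
#' @export
diag_t2 <- function(moments, genes) {
  stopifnot(inherits(moments, "group_moments"))
  idx <- resolve_genes(moments, genes)
  denom <- moments$diagvar_1[idx] / moments$n_1 +
    moments$diagvar_2[idx] / moments$n_2
  if (any(denom <= 0))
    stop("zero pooled scaled variance for gene(s): ",
         paste(moments$gene_ids[idx][denom <= 0], collapse = ", "))
  sum((moments$mean_1[idx] - moments$mean_2[idx])^2 / denom)
}

#' Full-covariance Hotelling-type T2 statistic for a gene subset
#'
#' The heteroscedastic Hotelling-type statistic
#' \deqn{T^2 = (\bar x_1 - \bar x_2)' (S_1/n_1 + S_2/n_2)^{-1}
#'   (\bar x_1 - \bar x_2)}
#' on the subset's genes, using the entire sample covariance matrices.
#' Requires the per-group sample size to exceed the subset size in practice;
#' an ill-conditioned combined matrix is refused rather than pseudo-inverted.
#'
#' @inheritParams diag_t2
#' @param cond_ceiling reject when the 2-norm condition number of
#'   `S_1/n_1 + S_2/n_2` exceeds this (default `1e12`).
#' @return a single non-negative number.
#' @export
full_t2 <- function(moments, genes, cond_ceiling = 1e12) {
  stopifnot(inherits(moments, "group_moments"))
  if (is.null(moments$cov_1) || is.null(moments$cov_2))
    stop("`moments` lacks full covariance matrices; rerun ",
         "compute_group_moments(study, with_full_cov = TRUE)")
  idx <- resolve_genes(moments, genes)
  w <- moments$cov_1[idx, idx, drop = FALSE] / moments$n_1 +
    moments$cov_2[idx, idx, drop = FALSE] / moments$n_2
  ev <- eigen(w, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_ceiling)
    stop("combined covariance matrix is singular or ill-conditioned ",
         "(condition number above ", format(cond_ceiling),
         "); refusing to pseudo-invert")
  d <- moments$mean_1[idx] - moments$mean_2[idx]
  drop(crossprod(d, solve(w, d)))
}

#' Paired-sample diagonal T2 statistic for a gene subset
#'
#' One-sample analogue of [diag_t2()] on per-pair differences: the sum over
#' the subset's genes of \eqn{n \bar d_g^2 / s^2_{d,g}}, where \eqn{\bar d_g}
#' is the mean difference for gene g, \eqn{s^2_{d,g}} its sample variance
#' and n the number of pairs. Each term is the squared one-sample t
#' statistic for the null of zero mean difference.
#'
#' @param differences numeric genes-by-pairs matrix of paired differences
#'   (see [paired_differences()]); needs at least 2 columns and row names.
#' @param genes gene identifiers or indices selecting the subset.
#' @return a single non-negative number.
#' @export
paired_diag_t2 <- function(differences, genes) {
  if (!is.matrix(differences) || ncol(differences) < 2L)
    stop("`differences` must be a matrix with at least 2 pairs")
  n <- ncol(differences)
  if (length(genes) == 0) stop("empty gene list")
  idx <- if (is.character(genes)) {
    i <- match(genes, rownames(differences))
    if (anyNA(i)) stop("unknown gene id(s): ",
                       paste(genes[is.na(i)], collapse = ", "))
    i
  } else as.integer(genes)
  d <- differences[idx, , drop = FALSE]
  dbar <- rowMeans(d)
  s2 <- rowSums((d - dbar)^2) / (n - 1)
  if (any(s2 <= 0))
    stop("zero variance of differences for gene(s): ",
         paste(rownames(differences)[idx][s2 <= 0], collapse = ", "))
  sum(n * dbar^2 / s2)
}
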