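#' Construct a two-group or paired expression study
#'
#' Bundles a genes-by-samples numeric matrix with its design. In two-group
#' mode every sample is assigned to one of two groups; in paired mode every
#' sample belongs to exactly one pair and carries one of two conditions
#' (e.g. baseline / follow-up), and inference is carried out on the per-pair
#' difference vectors.
#'
#' Input is validated strictly: non-finite expression values, duplicated
#' gene identifiers, or an incomplete design are rejected rather than
#' repaired. Missing values are never imputed.
#'
#' @param matrix numeric matrix, genes as rows and samples as columns.
#'   Row names are used as gene identifiers (required, unique); column
#'   names as sample identifiers.
#' @param group optional vector (length `ncol(matrix)`) with exactly two
#'   distinct labels assigning each sample to a group. The first label in
#'   sort order becomes group 1.
#' @param pair optional vector of pair identifiers (paired mode); each pair
#'   id must occur exactly twice.
#' @param condition optional vector of condition labels (paired mode),
#'   exactly two distinct values; within every pair both conditions must
#'   occur once. The first label in sort order is the baseline.
#' @return An object of class `expression_study` with elements `matrix`,
#'   `gene_ids`, `sample_ids`, `mode` (`"two_group"` or `"paired"`) and the
#'   design (`group` as an integer vector in \{1,2\}, or `pair`/`condition`).
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' study <- expression_study(m, group = c(1, 1, 1, 2, 2))
#' @export
expression_study <- function(matrix, group = NULL, pair = NULL,
                             condition = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(matrix)))
    stop("`matrix` must have row names (gene identifiers)")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicated gene identifiers: ",
         paste(unique(rownames(matrix)[duplicated(rownames(matrix))]),
               collapse = ", "))
  if (is.null(colnames(matrix)))
    colnames(matrix) <- paste0("sample", seq_len(ncol(matrix)))
  bad <- which(!is.finite(matrix), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite expression value at gene '",
         rownames(matrix)[bad[1, 1]], "', sample '",
         colnames(matrix)[bad[1, 2]], "' (missing values are not imputed)")

  if (!is.null(group) && (!is.null(pair) || !is.null(condition)))
    stop("supply either `group` (two-group mode) or `pair`+`condition` ",
         "(paired mode), not both")

  if (!is.null(group)) {
    if (length(group) != ncol(matrix))
      stop("`group` must have one entry per sample")
    labs <- sort(unique(as.character(group)))
    if (length(labs) != 2L)
      stop("`group` must contain exactly two distinct labels, found ",
           length(labs))
    gi <- match(as.character(group), labs)
    if (sum(gi == 1L) < 2L || sum(gi == 2L) < 2L)
      stop("each group needs at least 2 samples")
    out <- structure(
      list(matrix = matrix, gene_ids = rownames(matrix),
           sample_ids = colnames(matrix), mode = "two_group",
           group = gi, group_labels = labs),
      class = "expression_study")
    return(out)
  }

  if (is.null(pair) || is.null(condition))
    stop("paired mode needs both `pair` and `condition`")
  if (length(pair) != ncol(matrix) || length(condition) != ncol(matrix))
    stop("`pair` and `condition` must have one entry per sample")
  conds <- sort(unique(as.character(condition)))
  if (length(conds) != 2L)
    stop("`condition` must contain exactly two distinct labels")
  tab <- table(as.character(pair))
  if (any(tab != 2L))
    stop("every pair id must occur exactly twice; offending: ",
         paste(names(tab)[tab != 2L], collapse = ", "))
  split_cond <- split(as.character(condition), as.character(pair))
  incomplete <- names(split_cond)[!vapply(split_cond, function(x)
    setequal(x, conds), logical(1))]
  if (length(incomplete) > 0)
    stop("pairs missing one condition: ", paste(incomplete, collapse = ", "))
  if (length(tab) < 2L) stop("at least 2 complete pairs are required")
  structure(
    list(matrix = matrix, gene_ids = rownames(matrix),
         sample_ids = colnames(matrix), mode = "paired",
         pair = as.character(pair), condition = as.character(condition),
         condition_labels = conds),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples,", x$mode, "design\n")
  if (x$mode == "two_group") {
    cat("  group sizes:", sum(x$group == 1L), "/", sum(x$group == 2L), "\n")
  } else {
    cat("  pairs:", length(unique(x$pair)), "\n")
  }
  invisible(x)
}

#' Per-pair difference matrix of a paired study
#'
#' Returns the genes-by-pairs matrix of differences (second condition minus
#' baseline, conditions in label sort order), the input on which the paired
#' one-sample statistic operates.
#'
#' @param study an [expression_study()] in paired mode.
#' @return numeric matrix, genes x pairs; column names are pair ids.
#' @export
paired_differences <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (study$mode != "paired") stop("`study` is not a paired design")
  pairs <- unique(study$pair)
  base <- study$condition_labels[1]
  d <- vapply(pairs, function(p) {
    idx <- which(study$pair == p)
    i_base <- idx[study$condition[idx] == base]
    i_fup <- idx[study$condition[idx] != base]
    study$matrix[, i_fup] - study$matrix[, i_base]
  }, numeric(nrow(study$matrix)))
  d <- base::matrix(d, nrow = nrow(study$matrix),
                    dimnames = list(study$gene_ids, pairs))
  d
}

# Columns of the expression matrix belonging to group i (two-group mode).
group_columns <- function(study, i) {
  study$matrix[, study$group == i, drop = FALSE]
}
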