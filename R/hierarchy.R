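#' Construct a two-level set/subset hierarchy
#'
#' A hierarchy is an ordered collection of K named gene sets, each a union
#' of one or more named, non-empty subsets. Subsets within a set may
#' overlap; a set's gene content is always derived as the union of its
#' subsets and never stored separately.
#'
#' @param sets a named list; each element is itself a named list of
#'   character vectors (gene identifiers), one per subset.
#' @return An object of class `gene_set_hierarchy` with elements `sets`,
#'   `K` (number of sets) and `m` (integer vector, subsets per set).
#' @examples
#' h <- gene_set_hierarchy(list(
#'   pathwayA = list(sub1 = c("g1", "g2"), sub2 = c("g2", "g3")),
#'   pathwayB = list(sub1 = c("g4", "g5", "g6"))))
#' @export
gene_set_hierarchy <- function(sets) {
  if (!is.list(sets) || length(sets) < 1L)
    stop("`sets` must be a non-empty list of sets")
  if (is.null(names(sets)) || any(names(sets) == "") ||
      anyDuplicated(names(sets)))
    stop("sets must have unique non-empty names")
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    if (!is.list(s) || length(s) < 1L)
      stop("set '", names(sets)[k], "' must contain at least one subset")
    if (is.null(names(s)) || any(names(s) == "") || anyDuplicated(names(s)))
      stop("subsets of set '", names(sets)[k],
           "' must have unique non-empty names")
    for (j in seq_along(s)) {
      g <- s[[j]]
      if (!is.character(g) || length(g) < 1L)
        stop("subset '", names(s)[j], "' of set '", names(sets)[k],
             "' must be a non-empty character vector of gene ids")
      if (anyDuplicated(g))
        stop("subset '", names(s)[j], "' of set '", names(sets)[k],
             "' lists duplicate genes")
    }
  }
  structure(list(sets = sets, K = length(sets),
                 m = vapply(sets, length, integer(1))),
            class = "gene_set_hierarchy")
}

#' @export
print.gene_set_hierarchy <- function(x, ...) {
  cat("gene_set_hierarchy: K =", x$K, "sets;",
      sum(x$m), "subsets;", length(hierarchy_genes(x)), "distinct genes\n")
  invisible(x)
}

#' Union of all gene identifiers in a hierarchy (or one of its sets)
#'
#' @param hierarchy a [gene_set_hierarchy()].
#' @param set optional set name; if given, only that set's union.
#' @return character vector of distinct gene ids.
#' @export
hierarchy_genes <- function(hierarchy, set = NULL) {
  stopifnot(inherits(hierarchy, "gene_set_hierarchy"))
  src <- if (is.null(set)) unlist(hierarchy$sets, recursive = FALSE,
                                  use.names = FALSE)
         else hierarchy$sets[[set]]
  unique(unlist(src, use.names = FALSE))
}

# Resolve every subset's gene ids against a vector of known ids, erroring on
# any that do not resolve. Returns a list (one element per set) of lists of
# integer index vectors into `gene_ids`.
resolve_hierarchy <- function(hierarchy, gene_ids) {
  missing <- setdiff(hierarchy_genes(hierarchy), gene_ids)
  if (length(missing) > 0)
    stop("gene ids in the hierarchy absent from the expression matrix: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)",
                                           length(missing) - 10) else "")
  lapply(hierarchy$sets, function(s)
    lapply(s, function(g) match(g, gene_ids)))
}

# Flatten a hierarchy into parallel vectors (set, subset) plus a flat list
# of index vectors; used by the bootstrap engine and the report builder.
flatten_hierarchy <- function(hierarchy, gene_ids) {
  idx <- resolve_hierarchy(hierarchy, gene_ids)
  set_names <- rep(names(hierarchy$sets), times = hierarchy$m)
  subset_names <- unlist(lapply(hierarchy$sets, names), use.names = FALSE)
  list(set = set_names, subset = subset_names,
       index = unlist(idx, recursive = FALSE, use.names = FALSE))
}
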