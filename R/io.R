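#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. Input is validated strictly: ragged rows, non-numeric or
#' missing cells, and duplicated gene identifiers are rejected with the
#' offending gene/sample named — never coerced or imputed.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated (override with `sep`).
#' @param sep optional field separator.
#' @return list with `matrix` (numeric, genes x samples, dimnames set),
#'   `gene_ids`, `sample_ids`.
#' @export
read_expression <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L)
    stop("expression file needs a gene-id column and at least 2 samples")
  gene_ids <- raw[[1]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  sample_ids <- colnames(raw)[-1]
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(gene_ids, sample_ids))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric or missing value at gene '", gene_ids[bad[1, 1]],
         "', sample '", sample_ids[bad[1, 2]], "' in ", path)
  list(matrix = vals, gene_ids = gene_ids, sample_ids = sample_ids)
}

#' Write an expression matrix as TSV/CSV
#'
#' @param matrix numeric matrix with gene row names and sample column names.
#' @param path output path; `.csv` writes comma-separated.
#' @param sep optional field separator override.
#' @export
write_expression <- function(matrix, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    "," else "\t"
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a design file
#'
#' A header plus one row per sample: `sample_id<TAB>group` (two-group mode)
#' or `sample_id<TAB>pair<TAB>condition` (paired mode).
#'
#' @param path file path (tab-separated).
#' @return data.frame with columns `sample_id` and either `group` or
#'   `pair` + `condition`.
#' @export
read_design <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) == 2L) names(d) <- c("sample_id", "group")
  else if (ncol(d) == 3L) names(d) <- c("sample_id", "pair", "condition")
  else stop("design file must have 2 (two-group) or 3 (paired) columns")
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample id(s) in design: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  d
}

# Attach a design to a matrix, checking sample coverage both ways.
study_from_files <- function(expr, design) {
  missing <- setdiff(expr$sample_ids, design$sample_id)
  if (length(missing) > 0)
    stop("samples absent from the design file: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(design$sample_id, expr$sample_ids)
  if (length(extra) > 0)
    stop("design samples absent from the expression matrix: ",
         paste(extra, collapse = ", "))
  design <- design[match(expr$sample_ids, design$sample_id), , drop = FALSE]
  if ("group" %in% names(design))
    expression_study(expr$matrix, group = design$group)
  else
    expression_study(expr$matrix, pair = design$pair,
                     condition = design$condition)
}

#' Read a two-level set/subset hierarchy file
#'
#' Format (a two-level GMT dialect, defined here because plain GMT cannot
#' encode subset-within-set structure): one subset per line,
#' `set_name<TAB>subset_name<TAB>gene1<TAB>gene2...`; `#` starts a comment
#' line; UTF-8. Subsets of a set may share genes; `(set, subset)` pairs
#' must be unique.
#'
#' @param path file path.
#' @param known_gene_ids optional character vector to resolve gene ids
#'   against. In strict mode (default) an unknown gene is an error; with
#'   `strict = FALSE` unknown genes are dropped with a warning, and a
#'   subset left empty is still an error.
#' @param strict logical, see above.
#' @return a [gene_set_hierarchy()], sets in first-appearance order.
#' @export
read_set_hierarchy <- function(path, known_gene_ids = NULL, strict = TRUE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) stop("no subset lines in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0)
    stop("line ", short[1], " of ", path,
         " has fewer than 3 fields (set, subset, >=1 gene)")
  set_names <- vapply(parts, `[[`, character(1), 1L)
  subset_names <- vapply(parts, `[[`, character(1), 2L)
  key <- paste(set_names, subset_names, sep = "\t")
  if (anyDuplicated(key))
    stop("duplicate (set, subset) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  genes <- lapply(parts, function(p) unique(p[-(1:2)]))
  if (!is.null(known_gene_ids)) {
    unknown <- setdiff(unlist(genes, use.names = FALSE), known_gene_ids)
    if (length(unknown) > 0) {
      if (strict)
        stop("unknown gene id(s) in ", path, ": ",
             paste(utils::head(unknown, 10), collapse = ", "),
             if (length(unknown) > 10)
               sprintf(" (and %d more)", length(unknown) - 10) else "")
      warning(length(unknown), " unknown gene id(s) dropped from ", path)
      genes <- lapply(genes, intersect, known_gene_ids)
      empty <- which(lengths(genes) == 0)
      if (length(empty) > 0)
        stop("subset '", subset_names[empty[1]], "' of set '",
             set_names[empty[1]], "' is empty after dropping unknown genes")
    }
  }
  sets <- lapply(split(seq_along(parts),
                       factor(set_names, levels = unique(set_names))),
                 function(i) stats::setNames(genes[i], subset_names[i]))
  gene_set_hierarchy(sets)
}

#' Write a hierarchy in the two-level set/subset format
#'
#' Inverse of [read_set_hierarchy()]; parse -> write -> parse is the
#' identity.
#'
#' @param hierarchy a [gene_set_hierarchy()].
#' @param path output path.
#' @export
write_set_hierarchy <- function(hierarchy, path) {
  stopifnot(inherits(hierarchy, "gene_set_hierarchy"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(hierarchy$sets))
    for (j in names(hierarchy$sets[[k]]))
      writeLines(paste(c(k, j, hierarchy$sets[[k]][[j]]), collapse = "\t"),
                 con)
  invisible(path)
}

#' Import a plain GMT file as a flat hierarchy
#'
#' Each GMT line (`name<TAB>description<TAB>genes...`) becomes a set with a
#' single subset carrying the set's name, so flat gene-set collections can
#' be tested with the same machinery (the Bonferroni factor is then m_k = 1
#' per set).
#'
#' @param path GMT file path.
#' @return a [gene_set_hierarchy()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop("GMT lines need name, description and >= 1 gene")
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate GMT set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(seq_along(parts), function(i)
    stats::setNames(list(unique(parts[[i]][-(1:2)])), nm[i]))
  names(sets) <- nm
  gene_set_hierarchy(sets)
}
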