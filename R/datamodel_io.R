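#' Construct an expression matrix
#'
#' A thin validated wrapper around a numeric genes-by-samples matrix of
#' non-negative, FPKM-like abundances. All deconvolution backends consume
#' this container.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids optional character vectors; default to the
#'   dimnames of `values`.
#' @return an object of class `expression_matrix` (a numeric matrix with
#'   validated dimnames).
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression matrix must have at least 1 gene and 1 sample")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  gene_ids <- trimws(as.character(gene_ids))
  sample_ids <- trimws(as.character(sample_ids))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 gene_ids[neg[1, 1]], sample_ids[neg[1, 2]]))
  if (anyNA(values)) stop("expression matrix contains missing values")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read a delimited expression table
#'
#' Reads a TSV/CSV table with a header row and an identifier column and
#' returns a validated [expression_matrix]. Duplicate gene rows are collapsed
#' by arithmetic mean (scale-preserving for FPKM) with a warning.
#'
#' @param path file path to a delimited text file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param sep field separator; guessed from the file extension by default.
#' @return an [expression_matrix], genes x samples.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows", "samples_in_rows"),
                                   sep = NULL) {
  orientation <- match.arg(orientation)
  df <- read_delim_table(path, sep)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty expression matrix in ", path)
  ids <- trimws(as.character(df[[1]]))
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- NULL
  if (orientation == "samples_in_rows") {
    values <- t(values)
    gene_ids <- colnames(df)[-1]
    sample_ids <- ids
  } else {
    gene_ids <- ids
    sample_ids <- colnames(df)[-1]
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative expression value at gene '%s', sample '%s' in %s",
                 gene_ids[neg[1, 1]], trimws(sample_ids)[neg[1, 2]], path))
  if (anyDuplicated(gene_ids)) {
    ndup <- sum(duplicated(gene_ids))
    warning(sprintf("%d duplicate gene row(s) collapsed by mean", ndup))
    values <- rowsum(values, group = gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
    gene_ids <- unique(gene_ids)
  }
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  expression_matrix(values)
}

#' Write an expression matrix as TSV
#'
#' @param x an [expression_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_delim_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    quote = "\"", comment.char = "", stringsAsFactors = FALSE)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids. Duplicate members within a set are dropped; the
#' order of sets is preserved.
#'
#' @param path path to a GMT file.
#' @return a `gene_set_collection`: named list of unique member gene id
#'   vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0)
    stop(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  names_ <- vapply(fields, function(f) trimws(f[1]), character(1))
  if (anyDuplicated(names_))
    stop("duplicate gene-set name: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(trimws(f[-(1:2)])))
  sets <- lapply(sets, function(s) s[nzchar(s)])
  if (any(lengths(sets) < 1L)) stop("gene set with no members")
  names(sets) <- names_
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, function(f) f[2], character(1)), names_)
  class(sets) <- "gene_set_collection"
  sets
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, %d-%d members\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Construct a grouped signature matrix
#'
#' A marker-gene by cell-type reference with one group label per cell type
#' (the LM22-style layout: 22 leukocyte subsets in 7 functional groups).
#' The grouping drives the group penalty of the sparse group lasso.
#'
#' @param values non-negative numeric matrix, marker genes x cell types.
#' @param groups named character vector mapping every cell-type column to a
#'   group label.
#' @return an object of class `signature_matrix` with elements `values`
#'   (matrix) and `groups` (named character).
#' @export
signature_matrix <- function(values, groups) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("signature matrix needs gene row names and cell-type column names")
  if (any(values < 0)) stop("signature matrix has negative entries")
  ct <- colnames(values)
  if (!all(ct %in% names(groups)))
    stop("cell type(s) missing from groups: ",
         paste(setdiff(ct, names(groups)), collapse = ", "))
  groups <- groups[ct]
  structure(list(values = values, groups = groups),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d genes x %d cell types in %d groups\n",
              nrow(x$values), ncol(x$values), length(unique(x$groups))))
  invisible(x)
}

#' Read a signature matrix and its group file
#'
#' @param matrix_path delimited genes x cell-types table (id column first).
#' @param groups_path two-column delimited table: cell type, group label.
#' @return a [signature_matrix].
#' @export
read_signature_matrix <- function(matrix_path, groups_path) {
  df <- read_delim_table(matrix_path)
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- trimws(as.character(df[[1]]))
  gdf <- read_delim_table(groups_path)
  if (ncol(gdf) < 2L) stop("groups file needs two columns: cell type, group")
  groups <- stats::setNames(trimws(as.character(gdf[[2]])),
                            trimws(as.character(gdf[[1]])))
  unknown <- setdiff(names(groups), colnames(values))
  if (length(unknown) > 0)
    stop("groups file lists unknown cell type column(s): ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing) > 0)
    stop("cell type(s) missing from groups file: ",
         paste(missing, collapse = ", "))
  empty <- setdiff(unique(trimws(as.character(gdf[[2]]))), groups)
  if (length(empty) > 0)
    warning("group label(s) used by zero cell types: ",
            paste(empty, collapse = ", "))
  signature_matrix(values, groups)
}

#' Read the cell-type harmonization map
#'
#' The map links every (tool, tool cell-type name) pair to one canonical
#' cell-type name and carries, per canonical name, a lineage flag
#' (`myeloid`, `lymphoid`, `stromal` or `other`) and a class
#' (`cell_type` or `process`). A versioned default covering the cell types
#' used throughout the package ships in `inst/extdata/celltype_mapping.tsv`
#' and is user-extensible.
#'
#' @param path TSV with columns `tool`, `tool_celltype`, `canonical`,
#'   `lineage`, `class`; defaults to the shipped map.
#' @return a `celltype_mapping` data frame.
#' @export
read_celltype_mapping <- function(path = system.file("extdata", "celltype_mapping.tsv",
                                                     package = "iscores")) {
  df <- read_delim_table(path)
  required <- c("tool", "tool_celltype", "canonical", "lineage", "class")
  miss <- setdiff(required, colnames(df))
  if (length(miss) > 0)
    stop("mapping file missing column(s): ", paste(miss, collapse = ", "))
  df[required] <- lapply(df[required], function(x) trimws(as.character(x)))
  if (!all(df$lineage %in% c("myeloid", "lymphoid", "stromal", "other")))
    stop("lineage must be one of myeloid, lymphoid, stromal, other")
  if (!all(df$class %in% c("cell_type", "process")))
    stop("class must be cell_type or process")
  lin <- unique(df[, c("canonical", "lineage", "class")])
  if (anyDuplicated(lin$canonical))
    stop("canonical cell type with conflicting lineage/class annotation: ",
         paste(unique(lin$canonical[duplicated(lin$canonical)]), collapse = ", "))
  class(df) <- c("celltype_mapping", "data.frame")
  df
}

#' Read a clinical table
#'
#' Requires `sample_id`, `time` (non-negative, days) and `event` (0/1)
#' columns; optional covariate columns (`cancer_type`, `subtype`,
#' `localization`, `age`, `gender`, `stage`, `os_time`, `os_event`) pass
#' through. Rows with missing time or event are dropped with a message.
#'
#' @param path delimited text file.
#' @return a `clinical_table` data frame; the number of dropped rows is in
#'   attribute `n_dropped`.
#' @export
read_clinical_table <- function(path) {
  df <- read_delim_table(path)
  for (col in c("sample_id", "time", "event"))
    if (!col %in% colnames(df)) stop("clinical table missing column: ", col)
  df$time <- suppressWarnings(as.numeric(df$time))
  df$event <- suppressWarnings(as.numeric(df$event))
  keep <- !is.na(df$time) & !is.na(df$event)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " clinical row(s) dropped for missing time/event")
  df <- df[keep, , drop = FALSE]
  validate_clinical(df)
  attr(df, "n_dropped") <- n_dropped
  class(df) <- c("clinical_table", "data.frame")
  df
}

validate_clinical <- function(df) {
  if (any(df$time < 0)) stop("negative survival time")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  invisible(df)
}

#' Read a mutation table
#'
#' Requires `sample_id` and `gene`; optional `variant` (e.g. `p.S249`),
#' `mutation_count` (per-sample total, synonymous plus non-synonymous),
#' `msi_h` and `pole` flags (0/1).
#'
#' @param path delimited text file.
#' @return a `mutation_table` data frame (variant labels verbatim).
#' @export
read_mutation_table <- function(path) {
  df <- read_delim_table(path)
  for (col in c("sample_id", "gene"))
    if (!col %in% colnames(df)) stop("mutation table missing column: ", col)
  if ("mutation_count" %in% colnames(df)) {
    df$mutation_count <- as.numeric(df$mutation_count)
    if (any(df$mutation_count < 0, na.rm = TRUE)) stop("negative mutation count")
  }
  for (fl in c("msi_h", "pole"))
    if (fl %in% colnames(df) && !all(df[[fl]] %in% c(0, 1, NA)))
      stop(fl, " flag must be 0/1")
  class(df) <- c("mutation_table", "data.frame")
  df
}

#' Validate a file against one of the pipeline's input kinds
#'
#' Convenience wrapper used by the command-line `io validate` entry point.
#'
#' @param path input file.
#' @param kind one of `"expr"`, `"gmt"`, `"signature"` (expects
#'   `path` and `paste0(path, ".groups")`), `"clinical"`, `"mutation"`.
#' @return `TRUE` invisibly on success; errors describe the violation.
#' @export
validate_input <- function(path, kind = c("expr", "gmt", "signature",
                                          "clinical", "mutation")) {
  kind <- match.arg(kind)
  switch(kind,
    expr = read_expression_matrix(path),
    gmt = read_gmt(path),
    signature = read_signature_matrix(path, paste0(path, ".groups")),
    clinical = read_clinical_table(path),
    mutation = read_mutation_table(path))
  invisible(TRUE)
}
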