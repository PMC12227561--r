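#' Construct a per-tool estimate table
#'
#' Raw per-sample, per-cell-type abundance estimates from one deconvolution
#' source (a backend of this package or an external tool).
#'
#' @param values numeric matrix, samples x cell types, with dimnames.
#' @param tool_name the producing tool's name.
#' @param unmapped optional character vector of cell-type columns that a
#'   harmonization map could not resolve.
#' @return an object of class `estimate_table`.
#' @export
estimate_table <- function(values, tool_name, unmapped = character()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("estimate table needs sample row names and cell-type column names")
  if (anyDuplicated(rownames(values))) stop("duplicate sample rows")
  if (anyDuplicated(colnames(values))) stop("duplicate cell-type columns")
  structure(values, tool_name = tool_name, unmapped = unmapped,
            class = c("estimate_table", "matrix", "array"))
}

#' @export
print.estimate_table <- function(x, ...) {
  cat(sprintf("<estimate_table> tool=%s, %d samples x %d cell types\n",
              attr(x, "tool_name"), nrow(x), ncol(x)))
  invisible(x)
}

#' Non-negative least-squares deconvolution baseline
#'
#' Per-sample Lawson-Hanson non-negative least squares of expression on the
#' signature columns over the gene intersection; the stand-in for
#' reference-matrix-based backends.
#'
#' @inheritParams deconvolve_sgl
#' @return an [estimate_table()] with `tool_name = "NNLS"`.
#' @export
nnls_deconvolve <- function(expr, sig, min_overlap = 30L) {
  stopifnot(inherits(sig, "signature_matrix"))
  genes <- intersect(rownames(expr), rownames(sig$values))
  if (length(genes) < min_overlap)
    stop("only ", length(genes), " signature genes overlap expression (need >= ",
         min_overlap, ")")
  X <- sig$values[genes, , drop = FALSE]
  E <- unclass(expr)[genes, , drop = FALSE]
  est <- t(apply(E, 2, function(y) pracma::lsqnonneg(X, y)$x))
  dimnames(est) <- list(colnames(E), colnames(X))
  estimate_table(est, tool_name = "NNLS")
}

#' Ingest an external tool's estimate table
#'
#' Reads a samples x cell-types table produced by an external deconvolution
#' tool (e.g. absolute-mode support-vector regression scores). Values pass
#' through unchanged; tool cell-type names are retained and names absent
#' from the harmonization map are flagged, not dropped.
#'
#' @param path delimited table, samples in rows (id column first).
#' @param tool_name name under which the tool appears in the mapping.
#' @param mapping optional `celltype_mapping`; used only to flag unmapped
#'   cell-type columns.
#' @return an [estimate_table()].
#' @export
ingest_external_estimates <- function(path, tool_name, mapping = NULL) {
  df <- read_delim_table(path)
  ids <- trimws(as.character(df[[1]]))
  if (anyDuplicated(ids)) stop("duplicate sample rows in ", path)
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  unmapped <- character()
  if (!is.null(mapping)) {
    known <- mapping$tool_celltype[mapping$tool == tool_name]
    unmapped <- setdiff(colnames(values), known)
  }
  estimate_table(values, tool_name = tool_name, unmapped = unmapped)
}

#' Write an estimate table as TSV
#'
#' The first line records the producing tool as `# tool=<name>`.
#'
#' @param x an `estimate_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_estimate_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# tool=", attr(x, "tool_name")), con)
  df <- data.frame(sample_id = rownames(x),
                   as.data.frame(unclass(x), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
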