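#' Standardize a tool's estimates across samples
#'
#' Converts each cell-type column to a z-score over all samples:
#' `(x - mean(x)) / sd(x)` with the sample standard deviation (ddof = 1).
#' Zero-variance columns carry no cross-sample information and are dropped
#' with a warning.
#'
#' @param est an `estimate_table`.
#' @return a `standardized_table` (same shape minus dropped columns); each
#'   retained column has mean 0 and sd 1.
#' @export
standardize_estimates <- function(est) {
  stopifnot(inherits(est, "estimate_table"))
  if (nrow(est) < 2L) stop("standardization needs >= 2 samples (sd undefined)")
  v <- unclass(est)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(v)[sds == 0], collapse = ", "))
    v <- v[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(v) == 0L) stop("all columns have zero variance")
  z <- scale(v, center = TRUE, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  structure(z, tool_name = attr(est, "tool_name"),
            class = c("standardized_table", "matrix", "array"))
}

#' Harmonize standardized tables onto the canonical cell-type vocabulary
#'
#' Renames every tool's cell-type columns to canonical names via the
#' mapping. When two columns of one tool map to the same canonical name
#' they are first averaged within that tool. Unmapped columns are excluded
#' from integration but returned in an `unmapped` attribute per table.
#'
#' @param tables list of `standardized_table` objects.
#' @param mapping a `celltype_mapping` (see [read_celltype_mapping()]).
#' @return list of harmonized tables (columns = canonical names), each
#'   retaining its `tool_name`; unmapped columns in `attr(, "unmapped")`.
#' @export
harmonize <- function(tables, mapping) {
  lapply(tables, function(tab) {
    tool <- attr(tab, "tool_name")
    sub <- mapping[mapping$tool == tool, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("no mapping entries for tool '", tool, "'")
    canon <- sub$canonical[match(colnames(tab), sub$tool_celltype)]
    mapped <- !is.na(canon)
    unmapped <- unclass(tab)[, !mapped, drop = FALSE]
    if (ncol(unmapped) > 0)
      warning("tool '", tool, "': unmapped column(s) excluded from integration: ",
              paste(colnames(unmapped), collapse = ", "))
    v <- unclass(tab)[, mapped, drop = FALSE]
    colnames(v) <- canon[mapped]
    if (anyDuplicated(colnames(v))) {
      v <- t(rowsum(t(v), group = colnames(v), reorder = FALSE) /
               as.vector(table(factor(colnames(v), levels = unique(colnames(v))))))
    }
    structure(v, tool_name = tool, unmapped = unmapped,
              class = c("standardized_table", "matrix", "array"))
  })
}

#' Average harmonized z-scores into integrated scores (iScores)
#'
#' Per (sample, canonical cell type), the iScore is the arithmetic mean of
#' the z-scores from every tool that reports that cell type; a cell type
#' measured by one tool keeps that tool's z-score unchanged. Provenance
#' records which tools contributed to each cell type.
#'
#' @param tables list of harmonized `standardized_table` objects on an
#'   identical sample set (see [harmonize()]).
#' @return an `iscore_matrix` (samples x canonical cell types) with a
#'   `provenance` attribute.
#' @export
compute_iscores <- function(tables) {
  if (length(tables) < 1L) stop("need at least one table")
  samples <- rownames(tables[[1]])
  for (tab in tables[-1]) {
    if (!setequal(rownames(tab), samples))
      stop("sample-set mismatch across tools; differing samples: ",
           paste(union(setdiff(rownames(tab), samples),
                       setdiff(samples, rownames(tab))), collapse = ", "))
  }
  celltypes <- unique(unlist(lapply(tables, colnames)))
  acc <- matrix(0, length(samples), length(celltypes),
                dimnames = list(samples, celltypes))
  cnt <- matrix(0L, length(samples), length(celltypes),
                dimnames = list(samples, celltypes))
  for (tab in tables) {
    v <- unclass(tab)[samples, , drop = FALSE]
    acc[, colnames(v)] <- acc[, colnames(v)] + v
    cnt[, colnames(v)] <- cnt[, colnames(v)] + 1L
  }
  iscores <- acc / cnt
  provenance <- lapply(stats::setNames(celltypes, celltypes), function(ct)
    unlist(lapply(tables, function(tab)
      if (ct %in% colnames(tab)) attr(tab, "tool_name") else NULL)))
  structure(iscores, provenance = provenance,
            class = c("iscore_matrix", "matrix", "array"))
}

#' @export
print.iscore_matrix <- function(x, ...) {
  cat(sprintf("<iscore_matrix> %d samples x %d cell types\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Leukocyte and stromal aggregate scores
#'
#' The leukocyte score of a sample is the mean of all underlying
#' standardized (tool-level) scores of cell types in the myeloid or
#' lymphoid lineage; the stromal score is the mean over the four stromal
#' types (fibroblasts, endothelial cells, pericytes, adipocytes).
#' Process-class signatures (e.g. a hypoxia program) contribute to
#' neither. Aggregates average the tool-level standardized columns, not
#' the already-averaged iScores.
#'
#' @param tables list of harmonized `standardized_table` objects.
#' @param mapping a `celltype_mapping` carrying lineage and class per
#'   canonical cell type.
#' @return data frame with `sample_id`, `Leukocyte_iScore`,
#'   `Stromal_iScore`; an aggregate with no contributing columns is `NA`
#'   and named in attribute `undefined`.
#' @export
aggregate_iscores <- function(tables, mapping) {
  ann <- unique(mapping[, c("canonical", "lineage", "class")])
  samples <- rownames(tables[[1]])
  gather <- function(keep_canon) {
    cols <- lapply(tables, function(tab) {
      v <- unclass(tab)[samples, colnames(tab) %in% keep_canon, drop = FALSE]
      v
    })
    do.call(cbind, cols)
  }
  is_ct <- ann$class == "cell_type"
  leuk_types <- ann$canonical[is_ct & ann$lineage %in% c("myeloid", "lymphoid")]
  strom_types <- ann$canonical[is_ct & ann$lineage == "stromal"]
  leuk_cols <- gather(leuk_types)
  strom_cols <- gather(strom_types)
  undefined <- character()
  leuk <- if (is.null(leuk_cols) || ncol(leuk_cols) == 0) {
    undefined <- c(undefined, "Leukocyte_iScore")
    rep(NA_real_, length(samples))
  } else rowMeans(leuk_cols)
  strom <- if (is.null(strom_cols) || ncol(strom_cols) == 0) {
    undefined <- c(undefined, "Stromal_iScore")
    rep(NA_real_, length(samples))
  } else rowMeans(strom_cols)
  if (length(undefined) > 0)
    warning("aggregate(s) undefined (no contributing cell types): ",
            paste(undefined, collapse = ", "))
  structure(data.frame(sample_id = samples, Leukocyte_iScore = leuk,
                       Stromal_iScore = strom, row.names = NULL),
            undefined = undefined)
}

#' Pearson correlation with pairwise missing-value removal
#'
#' @param x,y numeric vectors of equal length; pairs with a missing value
#'   are removed, at least 3 complete pairs required.
#' @return Pearson r in `[-1, 1]`; `NA` with a warning when either vector
#'   has zero variance.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

#' Compare deconvolution methods against known fractions
#'
#' Per (method, cell type), the Pearson correlation between estimates and
#' the true mixing fractions over shared samples. Per cell type, the
#' integrated method is flagged best-or-tied when no competitor beats it by
#' more than `tie_tol` in r.
#'
#' @param estimates named list of samples x cell-types matrices (one per
#'   method, `iscore_matrix` or `estimate_table` included).
#' @param truth samples x cell-types matrix of true fractions.
#' @param integrated name of the integrated method in `estimates`
#'   (default `"iScore"`).
#' @param tie_tol absolute r difference treated as a tie (default 0.005).
#' @return list with `correlations` (method x cell type matrix),
#'   `best_or_tied` (named logical per cell type) and `fraction_best_or_tied`.
#' @export
method_comparison <- function(estimates, truth, integrated = "iScore",
                              tie_tol = 0.005) {
  if (!integrated %in% names(estimates))
    stop("integrated method '", integrated, "' not among estimates")
  shared_ct <- Reduce(intersect, c(lapply(estimates, colnames),
                                   list(colnames(truth))))
  if (length(shared_ct) == 0L) stop("no shared cell types with truth")
  shared_s <- Reduce(intersect, c(lapply(estimates, rownames),
                                  list(rownames(truth))))
  r <- t(vapply(estimates, function(est) {
    vapply(shared_ct, function(ct)
      pearson_correlation(unclass(est)[shared_s, ct], truth[shared_s, ct]),
      numeric(1))
  }, numeric(length(shared_ct))))
  dimnames(r) <- list(names(estimates), shared_ct)
  best <- vapply(shared_ct, function(ct) {
    r[integrated, ct] >= max(r[, ct], na.rm = TRUE) - tie_tol
  }, logical(1))
  list(correlations = r, best_or_tied = best,
       fraction_best_or_tied = mean(best))
}

#' Build an identity harmonization map
#'
#' Convenience constructor for cohorts (e.g. synthetic benchmarks) where
#' every tool already reports the canonical cell-type names: each
#' (tool, cell type) pair maps to itself.
#'
#' @param tools tool names.
#' @param celltypes canonical cell-type names shared by all tools.
#' @param lineage lineage flag applied to all cell types, default
#'   `"lymphoid"`.
#' @return a `celltype_mapping` data frame.
#' @export
identity_mapping <- function(tools, celltypes, lineage = "lymphoid") {
  df <- expand.grid(tool = tools, tool_celltype = celltypes,
                    stringsAsFactors = FALSE)
  df$canonical <- df$tool_celltype
  df$lineage <- lineage
  df$class <- "cell_type"
  class(df) <- c("celltype_mapping", "data.frame")
  df
}

#' Run the full integration pipeline over several estimate tables
#'
#' Standardizes each table, harmonizes cell-type names, averages into
#' iScores and appends the leukocyte and stromal aggregates.
#'
#' @param estimates list of `estimate_table` objects.
#' @param mapping a `celltype_mapping`.
#' @return list with `iscores` (the `iscore_matrix`) and `aggregates`
#'   (data frame from [aggregate_iscores()]).
#' @export
integrate_estimates <- function(estimates, mapping) {
  std <- lapply(estimates, standardize_estimates)
  aligned <- harmonize(std, mapping)
  list(iscores = compute_iscores(aligned),
       aggregates = aggregate_iscores(aligned, mapping))
}
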