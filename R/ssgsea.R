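#' Single-sample gene-set enrichment scores
#'
#' Rank-based per-sample scoring of a gene set's coordinate up-regulation.
#' Within each sample, genes are ranked by expression (average ranks for
#' ties). Walking the gene list in decreasing rank order, an in-set gene
#' advances a weighted empirical CDF by `rank^tau / sum(in-set rank^tau)`
#' and an out-of-set gene advances the unweighted out-set ECDF by
#' `1/(N - |S|)`; the score is the integrated (summed) difference between
#' the two running CDFs. Being rank-based, the score is invariant to any
#' strictly increasing per-sample transform of expression.
#'
#' @param expr an [expression_matrix].
#' @param sets a `gene_set_collection` (see [read_gmt()]) or a named list of
#'   gene id vectors.
#' @param tau rank-weighting exponent, default `0.25`.
#' @param normalize divide all scores by the overall `max - min` across
#'   samples and sets (default `TRUE`).
#' @param min_size sets with fewer present members are skipped with a
#'   warning (default 3).
#' @return an [estimate_table()] (samples x sets) with
#'   `tool_name = "ssGSEA"`.
#' @export
ssgsea_scores <- function(expr, sets, tau = 0.25, normalize = TRUE,
                          min_size = 3L) {
  genes <- rownames(expr)
  present <- lapply(sets, function(s) intersect(unique(s), genes))
  skip <- lengths(present) < min_size
  if (any(skip)) {
    warning("skipping set(s) with < ", min_size, " present members: ",
            paste(names(sets)[skip], collapse = ", "))
    present <- present[!skip]
  }
  if (length(present) == 0L) stop("no scorable gene sets")
  E <- unclass(expr)
  N <- nrow(E)
  in_set <- vapply(present, function(s) genes %in% s, logical(N))
  scores <- matrix(NA_real_, nrow = ncol(E), ncol = length(present),
                   dimnames = list(colnames(E), names(present)))
  for (j in seq_len(ncol(E))) {
    r <- rank(E[, j], ties.method = "average")
    ord <- order(-r, seq_len(N))       # decreasing rank, stable
    r_ord <- r[ord]
    w <- r_ord^tau
    for (k in seq_along(present)) {
      mem <- in_set[ord, k]
      n_in <- sum(mem)
      w_in <- numeric(N); w_in[mem] <- w[mem] / sum(w[mem])
      w_out <- numeric(N); w_out[!mem] <- 1 / (N - n_in)
      scores[j, k] <- sum(cumsum(w_in) - cumsum(w_out))
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  estimate_table(scores, tool_name = "ssGSEA")
}
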