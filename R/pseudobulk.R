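#' Simulate labeled single cells with cell-type marker structure
#'
#' Emulates a labeled scRNA-seq count matrix: every gene gets a log-normal
#' baseline mean; each cell type up-regulates its own block of marker genes
#' by `marker_fold`; counts are negative binomial with the given
#' dispersion (variance `mu + dispersion * mu^2`; `dispersion = 0` gives
#' Poisson counts). A fraction of cells has its label hidden to exercise
#' the classifier path (the truth is retained separately).
#'
#' @param n_types number of cell types.
#' @param n_genes total genes; must be >= `n_types * marker_count`.
#' @param cells_per_type cells simulated per type.
#' @param marker_count markers per type (disjoint blocks), default 20.
#' @param marker_fold mean fold-up of a type's markers in that type (> 1).
#' @param dispersion negative-binomial dispersion, default 0.5.
#' @param unlabeled_frac fraction of cells with hidden labels, default 0.
#' @param seed integer seed; the simulation is deterministic given it.
#' @return a `labeled_cell_matrix`: list with `counts` (genes x cells,
#'   integer), `labels` (observed; `"UNLABELED"` where hidden),
#'   `true_labels`, and `markers` (type -> marker gene ids).
#' @export
simulate_cells <- function(n_types, n_genes, cells_per_type,
                           marker_count = 20L, marker_fold = 8,
                           dispersion = 0.5, unlabeled_frac = 0,
                           seed = 1L) {
  if (n_types < 1L || n_genes < 1L || cells_per_type < 1L)
    stop("n_types, n_genes and cells_per_type must be positive")
  if (marker_count * n_types > n_genes)
    stop("marker_count * n_types exceeds n_genes")
  if (marker_fold <= 1) stop("marker_fold must be > 1")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (unlabeled_frac < 0 || unlabeled_frac >= 1)
    stop("unlabeled_frac must be in [0, 1)")
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  types <- sprintf("type%d", seq_len(n_types))
  base_mu <- stats::rlnorm(n_genes, meanlog = log(2), sdlog = 1)
  markers <- stats::setNames(lapply(seq_len(n_types), function(t)
    genes[((t - 1) * marker_count + 1):(t * marker_count)]), types)
  n_cells <- n_types * cells_per_type
  true_labels <- rep(types, each = cells_per_type)
  counts <- matrix(0L, n_genes, n_cells, dimnames = list(genes, NULL))
  for (t in seq_len(n_types)) {
    mu <- base_mu
    mi <- match(markers[[t]], genes)
    mu[mi] <- mu[mi] * marker_fold
    cols <- which(true_labels == types[t])
    draw <- if (dispersion == 0)
      stats::rpois(n_genes * length(cols), lambda = mu) else
      stats::rnbinom(n_genes * length(cols), mu = mu, size = 1 / dispersion)
    counts[, cols] <- matrix(as.integer(draw), n_genes, length(cols))
  }
  colnames(counts) <- sprintf("cell%05d", seq_len(n_cells))
  labels <- true_labels
  if (unlabeled_frac > 0) {
    hide <- sample(n_cells, round(unlabeled_frac * n_cells))
    labels[hide] <- "UNLABELED"
  }
  structure(list(counts = counts,
                 labels = stats::setNames(labels, colnames(counts)),
                 true_labels = stats::setNames(true_labels, colnames(counts)),
                 markers = markers),
            class = "labeled_cell_matrix")
}

#' @export
print.labeled_cell_matrix <- function(x, ...) {
  cat(sprintf("<labeled_cell_matrix> %d genes x %d cells, %d types (%d unlabeled)\n",
              nrow(x$counts), ncol(x$counts), length(x$markers),
              sum(x$labels == "UNLABELED")))
  invisible(x)
}

# library-size normalize to counts-per-10k, log1p
normalize_cells <- function(counts) {
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  log1p(sweep(counts, 2, lib, "/") * 1e4)
}

#' Label cells by marker-set expression
#'
#' Per cell, the score of each type is the mean across that type's markers
#' of per-gene z-scores of library-size-normalized log expression. A cell
#' is labeled with the arg-max type when the top score beats the runner-up
#' by at least `min_margin`, else it stays `UNLABELED`.
#'
#' @param cells a `labeled_cell_matrix` (its counts are used; its stored
#'   labels are ignored).
#' @param markers named list, type -> marker gene ids (disjoint sets).
#' @param min_margin required top-vs-runner-up score gap, default 0.1.
#' @return named character vector of labels per cell.
#' @export
label_by_markers <- function(cells, markers = cells$markers, min_margin = 0.1) {
  if (anyDuplicated(unlist(markers))) stop("marker sets must be disjoint")
  norm <- normalize_cells(cells$counts)
  z <- t(scale(t(norm)))
  z[is.nan(z)] <- 0
  scores <- vapply(markers, function(g) {
    g <- intersect(g, rownames(z))
    colMeans(z[g, , drop = FALSE])
  }, numeric(ncol(z)))
  labs <- apply(scores, 1, function(s) {
    o <- order(s, decreasing = TRUE)
    if (s[o[1]] - s[o[2]] >= min_margin) names(markers)[o[1]] else "UNLABELED"
  })
  stats::setNames(labs, colnames(cells$counts))
}

#' Shannon entropy of a vote vector
#'
#' Natural-log entropy of the empirical distribution of `k` categorical
#' predictions; ranges from 0 (all models agree) to `log(k)` (all
#' distinct).
#'
#' @param votes vector of predicted labels (one per model).
#' @return entropy in nats.
#' @export
vote_entropy <- function(votes) {
  p <- table(votes) / length(votes)
  -sum(p * log(p))
}

#' Classify unlabeled cells with an ensemble of linear classifiers
#'
#' Training cells are balanced by down-sampling every class to the median
#' class size; `k_models` linear support-vector classifiers are trained on
#' the k cross-validation complements of the balanced set; each unlabeled
#' cell gets k predictions. Cells whose vote-distribution Shannon entropy
#' exceeds `entropy_threshold` are flagged `AMBIGUOUS`; the rest receive
#' the majority label.
#'
#' @param cells a `labeled_cell_matrix`; cells labeled `"UNLABELED"` are
#'   the prediction set, all others the training set.
#' @param k_models ensemble size (= number of folds), default 5.
#' @param entropy_threshold ambiguity cutoff in nats, default `log(2)`.
#' @param seed integer seed (down-sampling and fold assignment).
#' @param features optional gene subset used as classifier input; defaults
#'   to the union of the marker genes.
#' @return data frame with `cell_id`, `label` (majority or `AMBIGUOUS`),
#'   `entropy`.
#' @export
classify_unlabeled <- function(cells, k_models = 5L,
                               entropy_threshold = log(2), seed = 1L,
                               features = unlist(cells$markers)) {
  if (k_models < 2L) stop("k_models must be >= 2")
  labs <- cells$labels
  train_ids <- names(labs)[labs != "UNLABELED"]
  pred_ids <- names(labs)[labs == "UNLABELED"]
  classes <- table(labs[train_ids])
  if (length(classes) < 2L) stop("need >= 2 labeled classes")
  if (any(classes == 0L)) stop("class with zero training cells")
  if (length(pred_ids) == 0L)
    return(data.frame(cell_id = character(), label = character(),
                      entropy = numeric()))
  set.seed(seed)
  med <- round(stats::median(classes))
  balanced <- unlist(lapply(names(classes), function(cl) {
    ids <- train_ids[labs[train_ids] == cl]
    if (length(ids) > med) sample(ids, med) else ids
  }))
  norm <- normalize_cells(cells$counts[features, , drop = FALSE])
  xtr <- t(norm[, balanced, drop = FALSE])
  ytr <- factor(labs[balanced])
  xpr <- t(norm[, pred_ids, drop = FALSE])
  fold <- sample(rep_len(seq_len(k_models), length(balanced)))
  votes <- vapply(seq_len(k_models), function(k) {
    fit <- e1071::svm(x = xtr[fold != k, , drop = FALSE], y = ytr[fold != k],
                      kernel = "linear", scale = FALSE)
    as.character(stats::predict(fit, xpr))
  }, character(length(pred_ids)))
  votes <- matrix(votes, nrow = length(pred_ids))
  ent <- apply(votes, 1, vote_entropy)
  majority <- apply(votes, 1, function(v) names(which.max(table(v))))
  data.frame(cell_id = pred_ids,
             label = ifelse(ent > entropy_threshold, "AMBIGUOUS", majority),
             entropy = ent, row.names = NULL)
}

#' Generate pseudobulk mixtures with known cell-type fractions
#'
#' Each pseudobulk is the gene-wise sum of the raw counts of
#' `round(cell_fraction * N)` cells drawn without replacement from the
#' labeled cells (defaults: 1000 pseudobulks, 10% of cells each). Cells
#' labeled `UNLABELED` or `AMBIGUOUS` are excluded before sampling. The
#' true fraction matrix records the sampled type composition of every
#' pseudobulk.
#'
#' @param cells a `labeled_cell_matrix`.
#' @param n_pseudobulks number of mixtures, default 1000.
#' @param cell_fraction fraction of available cells per mixture, default 0.10.
#' @param seed integer seed.
#' @return a `pseudobulk_set`: list with `mixtures` (an
#'   [expression_matrix], genes x pseudobulks), `true_fractions`
#'   (pseudobulks x types, rows sum to 1), `cells_used`, `seed`.
#' @export
make_pseudobulks <- function(cells, n_pseudobulks = 1000L,
                             cell_fraction = 0.10, seed = 1L) {
  if (cell_fraction <= 0 || cell_fraction > 1)
    stop("cell_fraction must be in (0, 1]")
  keep <- !(cells$labels %in% c("UNLABELED", "AMBIGUOUS"))
  counts <- cells$counts[, keep, drop = FALSE]
  labels <- cells$labels[keep]
  N <- ncol(counts)
  m <- round(cell_fraction * N)
  if (m < 1L) stop("cell_fraction * N < 1: no cells to draw")
  types <- sort(unique(labels))
  set.seed(seed)
  mix <- matrix(0, nrow(counts), n_pseudobulks,
                dimnames = list(rownames(counts),
                                sprintf("pb%04d", seq_len(n_pseudobulks))))
  fractions <- matrix(0, n_pseudobulks, length(types),
                      dimnames = list(colnames(mix), types))
  cells_used <- vector("list", n_pseudobulks)
  for (i in seq_len(n_pseudobulks)) {
    pick <- sample(N, m, replace = FALSE)
    mix[, i] <- rowSums(counts[, pick, drop = FALSE])
    fractions[i, ] <- tabulate(factor(labels[pick], levels = types),
                               nbins = length(types)) / m
    cells_used[[i]] <- colnames(counts)[pick]
  }
  structure(list(mixtures = expression_matrix(mix),
                 true_fractions = fractions,
                 cells_used = cells_used, seed = seed),
            class = "pseudobulk_set")
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat(sprintf("<pseudobulk_set> %d pseudobulks x %d genes, %d types\n",
              ncol(x$mixtures), nrow(x$mixtures), ncol(x$true_fractions)))
  invisible(x)
}

#' Location-only batch correction toward a reference
#'
#' For every gene shared with the reference, the batch mean is replaced by
#' the reference mean: `corrected = value - mean(batch) + mean(reference)`.
#' No variance scaling is applied, so the operation is idempotent. Genes
#' absent from the reference pass through unchanged with a warning.
#' Corrected values may leave the non-negative scale, so a plain matrix is
#' returned.
#'
#' @param pseudobulks genes x samples matrix (the batch to correct).
#' @param reference genes x samples matrix defining target per-gene means.
#' @return corrected numeric matrix, same shape as `pseudobulks`.
#' @export
mean_batch_correct <- function(pseudobulks, reference) {
  pb <- unclass(as.matrix(pseudobulks))
  ref <- unclass(as.matrix(reference))
  shared <- intersect(rownames(pb), rownames(ref))
  if (length(shared) == 0L) stop("no genes shared with reference")
  extra <- setdiff(rownames(pb), shared)
  if (length(extra) > 0)
    warning(length(extra), " gene(s) absent from reference passed through unchanged")
  out <- pb
  out[shared, ] <- pb[shared, , drop = FALSE] -
    rowMeans(pb[shared, , drop = FALSE]) +
    rowMeans(ref[shared, , drop = FALSE])
  out
}

#' Correlate estimates with true pseudobulk fractions
#'
#' @param estimates samples x cell-types matrix (`iscore_matrix` or
#'   `estimate_table`); cell-type names must match the truth columns.
#' @param true_fractions pseudobulks x cell-types truth matrix.
#' @param threshold reporting threshold on r for the `recovered` flag,
#'   default 0.5.
#' @return data frame with `celltype`, `r`, `recovered`; constant truth
#'   columns yield `NA` with a warning.
#' @export
score_recovery <- function(estimates, true_fractions, threshold = 0.5) {
  est <- unclass(as.matrix(estimates))
  shared_s <- intersect(rownames(est), rownames(true_fractions))
  if (length(shared_s) == 0L) stop("no shared samples with truth")
  shared_ct <- intersect(colnames(est), colnames(true_fractions))
  if (length(shared_ct) == 0L) stop("no shared cell types with truth")
  r <- vapply(shared_ct, function(ct) {
    tr <- true_fractions[shared_s, ct]
    if (stats::sd(tr) == 0) {
      warning("constant truth column '", ct, "': r undefined")
      return(NA_real_)
    }
    pearson_correlation(est[shared_s, ct], tr)
  }, numeric(1))
  data.frame(celltype = shared_ct, r = r,
             recovered = !is.na(r) & r >= threshold, row.names = NULL)
}

#' Build a signature matrix from labeled cells
#'
#' Per-type mean of library-size-normalized expression (counts per 10k)
#' over the chosen genes — the synthetic analogue of an LM22-style
#' reference for the regression backends.
#'
#' @param cells a `labeled_cell_matrix`.
#' @param genes gene subset; defaults to the union of all marker genes.
#' @param groups optional named group label per type; defaults to one
#'   group per type.
#' @return a [signature_matrix].
#' @export
signature_from_cells <- function(cells, genes = unlist(cells$markers),
                                 groups = NULL) {
  keep <- !(cells$labels %in% c("UNLABELED", "AMBIGUOUS"))
  norm <- normalize_cells(cells$counts[, keep, drop = FALSE])
  labels <- cells$labels[keep]
  types <- sort(unique(labels))
  genes <- intersect(genes, rownames(norm))
  values <- vapply(types, function(t)
    rowMeans(norm[genes, labels == t, drop = FALSE]),
    numeric(length(genes)))
  dimnames(values) <- list(genes, types)
  if (is.null(groups)) groups <- stats::setNames(types, types)
  signature_matrix(values, groups)
}
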