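#' Embed samples into a 2D TME map
#'
#' Lays out samples in two dimensions from their iScore vectors: a
#' k-nearest-neighbor graph under correlation distance is drawn with a
#' force-directed (Fruchterman-Reingold) layout. The layout is a
#' documented local substitute for web-service projections; its contract
#' is (a) determinism given `seed`, and (b) for well-separated groups in
#' iScore space, smaller mean within-group than between-group 2D
#' distances. Identical input profiles receive identical coordinates.
#'
#' @param iscores samples x cell-types matrix (`iscore_matrix` or plain);
#'   missing values are mean-imputed per column with a warning.
#' @param k_neighbors neighbors per sample in the graph, default 15.
#' @param seed integer seed for the layout.
#' @return data frame `sample_id`, `x`, `y` of class `tme_coords`.
#' @export
embed_iscores <- function(iscores, k_neighbors = 15L, seed = 1L) {
  v <- unclass(as.matrix(iscores))
  if (anyNA(v)) {
    warning("missing iScores mean-imputed per cell type")
    for (j in seq_len(ncol(v))) {
      nas <- is.na(v[, j])
      v[nas, j] <- mean(v[, j], na.rm = TRUE)
    }
  }
  key <- apply(v, 1, paste, collapse = "\r")
  uniq <- !duplicated(key)
  U <- v[uniq, , drop = FALSE]
  nu <- nrow(U)
  if (nu <= k_neighbors)
    stop("need more than k_neighbors (", k_neighbors, ") distinct samples, have ", nu)
  sds <- apply(U, 1, stats::sd)
  if (any(sds == 0))
    stop("sample(s) with constant iScore vector: correlation distance undefined")
  D <- 1 - stats::cor(t(U))
  el <- do.call(rbind, lapply(seq_len(nu), function(i) {
    nb <- order(D[i, ])[2:(k_neighbors + 1L)]
    cbind(i, nb, D[i, nb])
  }))
  und <- t(apply(el[, 1:2, drop = FALSE], 1, sort))
  keep <- !duplicated(und)
  g <- igraph::graph_from_edgelist(und[keep, , drop = FALSE], directed = FALSE)
  igraph::E(g)$weight <- 1 / (el[keep, 3] + 1e-6)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, niter = 500, weights = igraph::E(g)$weight)
  coords <- xy[match(key, key[uniq]), , drop = FALSE]
  structure(data.frame(sample_id = rownames(v), x = coords[, 1],
                       y = coords[, 2], row.names = NULL),
            k_neighbors = k_neighbors, seed = seed,
            class = c("tme_coords", "data.frame"))
}

#' Cluster the TME map
#'
#' Density clustering of the 2D map coordinates with the in-package
#' HDBSCAN-family algorithm ([hdbscan_clusters()]); samples in no dense
#' region are labeled noise (cluster 0).
#'
#' @param coords a `tme_coords` data frame from [embed_iscores()], or any
#'   data frame with `sample_id`, `x`, `y`.
#' @param min_cluster_size minimum cluster size, default 20.
#' @param ... passed to [hdbscan_clusters()].
#' @return named integer vector of cluster labels (`0` = noise).
#' @export
cluster_map <- function(coords, min_cluster_size = 20L, ...) {
  xy <- as.matrix(coords[, c("x", "y")])
  labels <- hdbscan_clusters(xy, min_cluster_size = min_cluster_size, ...)
  sizes <- table(labels[labels > 0])
  stopifnot(all(sizes >= min_cluster_size))
  stats::setNames(labels, coords$sample_id)
}

#' Differential iScores between each smaller cluster and the largest
#'
#' Within each group (cancer type or subtype), every cluster with at least
#' `min_n` samples is compared to the group's largest cluster by a Welch
#' t-test per iScore. Each comparison reports the leukocyte aggregate row
#' plus the five smallest-p iScores.
#'
#' @param iscores samples x score-columns matrix; include the aggregate
#'   columns if they should be testable.
#' @param clusters named cluster labels from [cluster_map()]; noise (0)
#'   is ignored.
#' @param group_of optional named group label per sample; `NULL` treats
#'   all samples as one group.
#' @param leukocyte name of the always-reported column, default
#'   `"Leukocyte_iScore"` (skipped if absent).
#' @param min_n minimum samples per cluster side, default 5.
#' @param top_k number of top differential iScores reported, default 5.
#' @return data frame with `group`, `cluster`, `n_cluster`, `n_largest`,
#'   `celltype`, `t`, `p`, `reported_as` (`"leukocyte"` or `"top5"`).
#' @export
cluster_differentials <- function(iscores, clusters, group_of = NULL,
                                  leukocyte = "Leukocyte_iScore",
                                  min_n = 5L, top_k = 5L) {
  v <- unclass(as.matrix(iscores))
  samples <- intersect(rownames(v), names(clusters))
  v <- v[samples, , drop = FALSE]
  cl <- clusters[samples]
  grp <- if (is.null(group_of)) stats::setNames(rep("all", length(samples)), samples)
         else group_of[samples]
  out <- list()
  for (g in unique(grp)) {
    s <- samples[grp == g]
    tab <- table(cl[s][cl[s] > 0])
    tab <- tab[tab >= min_n]
    if (length(tab) < 2L) next
    largest <- as.integer(names(tab)[which.max(tab)])
    for (small in setdiff(as.integer(names(tab)), largest)) {
      a <- s[cl[s] == small]; b <- s[cl[s] == largest]
      if (length(a) < 2L || length(b) < 2L) {
        message("cluster with < 2 samples skipped in group ", g)
        next
      }
      tests <- lapply(colnames(v), function(ct) {
        ht <- tryCatch(stats::t.test(v[a, ct], v[b, ct]),
                       error = function(e) NULL)
        if (is.null(ht)) return(NULL)
        data.frame(group = g, cluster = small, n_cluster = length(a),
                   n_largest = length(b), celltype = ct,
                   t = unname(ht$statistic), p = ht$p.value)
      })
      tests <- do.call(rbind, tests)
      if (is.null(tests)) next
      top <- tests[tests$celltype != leukocyte, , drop = FALSE]
      top <- top[order(top$p), , drop = FALSE]
      top <- utils::head(top, top_k)
      top$reported_as <- "top5"
      if (leukocyte %in% tests$celltype) {
        lk <- tests[tests$celltype == leukocyte, , drop = FALSE]
        lk$reported_as <- "leukocyte"
        top <- rbind(lk, top)
      }
      out[[length(out) + 1L]] <- top
    }
  }
  if (length(out) == 0L)
    return(data.frame(group = character(), cluster = integer(),
                      n_cluster = integer(), n_largest = integer(),
                      celltype = character(), t = numeric(), p = numeric(),
                      reported_as = character()))
  do.call(rbind, out)
}

#' Survival separation between each smaller cluster and the largest
#'
#' Per group (cancer type), every cluster with at least `min_n` samples is
#' compared to the group's largest cluster with a Cox proportional-hazards
#' model of cluster membership adjusted for subtype; the separation
#' p-value is the two-group log-rank test. The endpoint is
#' progression-free survival (`time`/`event`); for cancers listed in
#' `no_pfs` with `os_time`/`os_event` columns present, overall survival is
#' substituted.
#'
#' @param clusters named cluster labels from [cluster_map()].
#' @param clinical a `clinical_table` (needs `sample_id`, `time`, `event`;
#'   optional `cancer_type`, `subtype`, `os_time`, `os_event`).
#' @param covariate covariate column adjusted for, default `"subtype"`
#'   (skipped when absent or constant).
#' @param group_col grouping column, default `"cancer_type"` (all samples
#'   form one group when absent).
#' @param min_n minimum samples per cluster side, default 5.
#' @param no_pfs cancer types lacking the progression endpoint, default
#'   `"LAML"`.
#' @return data frame with `group`, `cluster`, `n_cluster`, `n_largest`,
#'   `endpoint`, `hr`, `ci_low`, `ci_high`, `logrank_p`, `inestimable`.
#' @export
cluster_survival <- function(clusters, clinical, covariate = "subtype",
                             group_col = "cancer_type", min_n = 5L,
                             no_pfs = "LAML") {
  df <- as.data.frame(clinical)
  df <- df[df$sample_id %in% names(clusters), , drop = FALSE]
  df$cluster <- clusters[df$sample_id]
  df <- df[df$cluster > 0, , drop = FALSE]
  grp <- if (group_col %in% colnames(df)) df[[group_col]] else rep("all", nrow(df))
  out <- list()
  for (g in unique(grp)) {
    sub <- df[grp == g, , drop = FALSE]
    use_os <- g %in% no_pfs && all(c("os_time", "os_event") %in% colnames(sub))
    sub$.time <- if (use_os) as.numeric(sub$os_time) else sub$time
    sub$.event <- if (use_os) as.numeric(sub$os_event) else sub$event
    sub <- sub[!is.na(sub$.time) & !is.na(sub$.event), , drop = FALSE]
    tab <- table(sub$cluster)
    tab <- tab[tab >= min_n]
    if (length(tab) < 2L) next
    largest <- as.integer(names(tab)[which.max(tab)])
    for (small in setdiff(as.integer(names(tab)), largest)) {
      two <- sub[sub$cluster %in% c(small, largest), , drop = FALSE]
      two$in_small <- as.integer(two$cluster == small)
      res <- data.frame(group = g, cluster = small,
                        n_cluster = sum(two$in_small),
                        n_largest = sum(!two$in_small),
                        endpoint = if (use_os) "OS" else "PFS",
                        hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        logrank_p = NA_real_, inestimable = FALSE)
      if (sum(two$.event[two$in_small == 1]) == 0 ||
          sum(two$.event[two$in_small == 0]) == 0) {
        res$inestimable <- TRUE
        out[[length(out) + 1L]] <- res
        next
      }
      fml <- stats::as.formula(
        if (covariate %in% colnames(two) &&
            length(unique(two[[covariate]])) > 1L)
          paste("survival::Surv(.time, .event) ~ in_small +", covariate)
        else "survival::Surv(.time, .event) ~ in_small")
      fit <- tryCatch(survival::coxph(fml, data = two, ties = "efron"),
                      error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit)) {
        sm <- summary(fit)
        res$hr <- unname(sm$conf.int["in_small", "exp(coef)"])
        res$ci_low <- unname(sm$conf.int["in_small", "lower .95"])
        res$ci_high <- unname(sm$conf.int["in_small", "upper .95"])
      } else res$inestimable <- TRUE
      lr <- tryCatch(
        survival::survdiff(survival::Surv(.time, .event) ~ in_small, data = two),
        error = function(e) NULL)
      if (!is.null(lr))
        res$logrank_p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
      out[[length(out) + 1L]] <- res
    }
  }
  if (length(out) == 0L)
    return(data.frame(group = character(), cluster = integer(),
                      n_cluster = integer(), n_largest = integer(),
                      endpoint = character(), hr = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      logrank_p = numeric(), inestimable = logical()))
  do.call(rbind, out)
}
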