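#' Hierarchical density-based clustering with a minimum cluster size
#'
#' Density clustering in the HDBSCAN family: mutual-reachability distances
#' (pairwise distance floored by both points' core distances), a minimum
#' spanning tree of that graph, the single-linkage hierarchy of the tree,
#' a tree condensed at `min_cluster_size`, and excess-of-mass cluster
#' selection by stability. Points not absorbed by any selected cluster are
#' noise (label 0). Deterministic: no randomness is involved.
#'
#' @param x numeric matrix, observations in rows.
#' @param min_cluster_size smallest allowed cluster, default 20.
#' @param min_samples neighborhood size for the core distance (the
#'   k-th nearest neighbor, self included); defaults to `min_cluster_size`.
#' @param allow_single_cluster permit the hierarchy root itself to be
#'   selected (default `FALSE`).
#' @return integer vector of cluster labels (`0` = noise), one per row of
#'   `x`; every positive label has at least `min_cluster_size` members.
#' @export
hdbscan_clusters <- function(x, min_cluster_size = 20L,
                             min_samples = min_cluster_size,
                             allow_single_cluster = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (min_cluster_size < 2L) stop("min_cluster_size must be >= 2")
  if (n < min_cluster_size) return(rep(0L, n))
  D <- as.matrix(stats::dist(x))
  k <- min(min_samples, n)
  core <- apply(D, 1, function(row) sort(row, partial = k)[k])
  mreach <- pmax(D, outer(core, core, pmax))
  edges <- prim_mst(mreach)
  hc <- single_linkage(edges, n)
  cond <- condense_tree(hc, n, min_cluster_size)
  labels_from_condensed(cond, n, allow_single_cluster)
}

# O(n^2) Prim minimum spanning tree; returns (from, to, weight) rows
prim_mst <- function(D) {
  n <- nrow(D)
  in_tree <- rep(FALSE, n); in_tree[1] <- TRUE
  best <- D[1, ]; best_from <- rep(1L, n)
  edges <- matrix(0, n - 1L, 3L)
  for (m in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    edges[m, ] <- c(best_from[j], j, best[j])
    in_tree[j] <- TRUE
    upd <- which(!in_tree & D[j, ] < best)
    best[upd] <- D[j, upd]; best_from[upd] <- j
  }
  edges
}

# single-linkage dendrogram from MST edges via union-find
# returns list(left, right, height, size): children ids are 1..n for
# leaves, n+m for the internal node created at merge m
single_linkage <- function(edges, n) {
  edges <- edges[order(edges[, 3]), , drop = FALSE]
  parent <- seq_len(2L * n - 1L)
  node_of <- seq_len(n)          # current dendrogram node of each component root
  size <- c(rep(1L, n), rep(0L, n - 1L))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  left <- integer(n - 1L); right <- integer(n - 1L); height <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    ra <- find(edges[m, 1]); rb <- find(edges[m, 2])
    new_node <- n + m
    left[m] <- node_of[ra]; right[m] <- node_of[rb]
    height[m] <- edges[m, 3]
    size[new_node] <- size[node_of[ra]] + size[node_of[rb]]
    parent[ra] <- rb
    node_of[rb] <- new_node
  }
  list(left = left, right = right, height = height, size = size)
}

leaves_under <- function(node, hc, n) {
  out <- integer(0); stack <- node
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v)
    else {
      m <- v - n
      stack <- c(stack, hc$left[m], hc$right[m])
    }
  }
  out
}

# condense the dendrogram: clusters persist through splits that only shed
# fewer-than-min_cluster_size points; a split into two big children creates
# two new condensed clusters
condense_tree <- function(hc, n, mcs) {
  lambda_of <- function(h) if (h <= 0) Inf else 1 / h
  root_node <- 2L * n - 1L
  parent_cl <- integer(0); child_cl <- integer(0)
  cl_lambda <- numeric(0); cl_size <- integer(0)
  pt_cluster <- integer(0); pt_id <- integer(0); pt_lambda <- numeric(0)
  birth <- c(0)                       # cluster 1 = root
  n_clusters <- 1L
  stack <- list(list(node = root_node, cluster = 1L))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- top$node; cl <- top$cluster
    if (node <= n) {                  # bare leaf reached under its cluster
      pt_cluster <- c(pt_cluster, cl); pt_id <- c(pt_id, node)
      pt_lambda <- c(pt_lambda, Inf)
      next
    }
    m <- node - n
    lam <- lambda_of(hc$height[m])
    ch <- c(hc$left[m], hc$right[m])
    sizes <- hc$size[ch]
    if (all(sizes >= mcs)) {
      for (i in 1:2) {
        n_clusters <- n_clusters + 1L
        parent_cl <- c(parent_cl, cl); child_cl <- c(child_cl, n_clusters)
        cl_lambda <- c(cl_lambda, lam); cl_size <- c(cl_size, sizes[i])
        birth <- c(birth, lam)
        stack[[length(stack) + 1L]] <- list(node = ch[i], cluster = n_clusters)
      }
    } else {
      for (i in 1:2) {
        if (sizes[i] < mcs) {         # points shed from cl at this level
          pts <- leaves_under(ch[i], hc, n)
          pt_cluster <- c(pt_cluster, rep(cl, length(pts)))
          pt_id <- c(pt_id, pts)
          pt_lambda <- c(pt_lambda, rep(lam, length(pts)))
        } else {
          stack[[length(stack) + 1L]] <- list(node = ch[i], cluster = cl)
        }
      }
    }
  }
  list(parent_cl = parent_cl, child_cl = child_cl, cl_lambda = cl_lambda,
       cl_size = cl_size, pt_cluster = pt_cluster, pt_id = pt_id,
       pt_lambda = pt_lambda, birth = birth, n_clusters = n_clusters)
}

labels_from_condensed <- function(cond, n, allow_single_cluster) {
  nc <- cond$n_clusters
  # finite surrogate for points that never detach (identical coordinates)
  finite_lam <- cond$pt_lambda
  if (any(is.infinite(finite_lam))) {
    cap <- if (any(is.finite(c(cond$pt_lambda, cond$cl_lambda))))
      2 * max(c(cond$pt_lambda[is.finite(cond$pt_lambda)],
                cond$cl_lambda[is.finite(cond$cl_lambda)], 1)) else 1
    finite_lam[is.infinite(finite_lam)] <- cap
  }
  stability <- numeric(nc)
  for (i in seq_along(cond$pt_cluster)) {
    cl <- cond$pt_cluster[i]
    stability[cl] <- stability[cl] + (finite_lam[i] - cond$birth[cl])
  }
  for (i in seq_along(cond$child_cl)) {
    cl <- cond$parent_cl[i]
    stability[cl] <- stability[cl] +
      cond$cl_size[i] * (cond$cl_lambda[i] - cond$birth[cl])
  }
  children <- split(cond$child_cl, cond$parent_cl)
  sel_stab <- numeric(nc)
  selected <- logical(nc)
  for (cl in rev(seq_len(nc))) {
    kids <- children[[as.character(cl)]]
    if (is.null(kids)) {
      selected[cl] <- TRUE
      sel_stab[cl] <- stability[cl]
    } else if (stability[cl] >= sum(sel_stab[kids])) {
      selected[cl] <- TRUE
      sel_stab[cl] <- stability[cl]
    } else {
      selected[cl] <- FALSE
      sel_stab[cl] <- sum(sel_stab[kids])
    }
  }
  if (!allow_single_cluster) selected[1] <- FALSE
  # top-down: keep the shallowest selected cluster on each path
  final <- logical(nc)
  stack <- 1L
  while (length(stack) > 0) {
    cl <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (selected[cl]) final[cl] <- TRUE
    else {
      kids <- children[[as.character(cl)]]
      if (!is.null(kids)) stack <- c(stack, kids)
    }
  }
  # point membership: climb from the cluster a point fell out of to the
  # first finally-selected ancestor, if any
  parent_of <- integer(nc)
  parent_of[cond$child_cl] <- cond$parent_cl
  owner <- integer(nc)                 # 0 = noise
  for (cl in seq_len(nc)) {
    a <- cl
    while (a != 0L && !final[a]) a <- parent_of[a]
    owner[cl] <- a
  }
  labels <- rep(0L, n)
  lab_map <- stats::setNames(seq_along(which(final)), which(final))
  for (i in seq_along(cond$pt_id)) {
    o <- owner[cond$pt_cluster[i]]
    labels[cond$pt_id[i]] <- if (o == 0L) 0L else lab_map[[as.character(o)]]
  }
  labels
}
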