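#' Define a per-sample sparse-group-lasso problem
#'
#' One bulk sample's expression over the signature genes is regressed on the
#' signature columns (cell-type reference profiles) under a penalty that
#' mixes the lasso (within-group sparsity) and the group lasso
#' (between-group sparsity):
#' \deqn{\frac{1}{2n}\|y - \sum_l X^{(l)}\beta^{(l)}\|_2^2 +
#'   (1-\alpha)\lambda \sum_l \sqrt{p_l}\,\|\beta^{(l)}\|_2 +
#'   \alpha\lambda\|\beta\|_1}
#' where \eqn{p_l} is the size of group \eqn{l} and \eqn{n} the number of
#' signature genes.
#'
#' @param y numeric response vector (one sample over n signature genes).
#' @param X numeric n x p design (signature values).
#' @param groups group label per column of `X` (any atomic vector).
#' @param alpha mixing weight in `[0,1]`; `1` is the lasso, `0` the group
#'   lasso. Default `0.5`.
#' @param lambda penalty `>= 0`.
#' @return an object of class `sgl_problem`.
#' @export
sgl_problem <- function(y, X, groups, alpha = 0.5, lambda = 0) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (length(y) < 2L) stop("need at least 2 observations (signature genes)")
  if (length(groups) != ncol(X)) stop("one group label per column required")
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be in [0, 1]")
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("lambda must be >= 0")
  structure(list(y = y, X = X, groups = as.integer(factor(groups)),
                 group_labels = groups, alpha = alpha, lambda = lambda),
            class = "sgl_problem")
}

#' Evaluate the sparse-group-lasso objective
#'
#' @param beta coefficient vector, one entry per column of the design.
#' @param problem an [sgl_problem].
#' @return the penalized objective value (finite scalar).
#' @export
sgl_objective <- function(beta, problem) {
  stopifnot(inherits(problem, "sgl_problem"))
  if (length(beta) != ncol(problem$X))
    stop("beta has length ", length(beta), ", expected ", ncol(problem$X))
  n <- length(problem$y)
  r <- problem$y - drop(problem$X %*% beta)
  loss <- sum(r^2) / (2 * n)
  grp <- split(beta, problem$groups)
  group_pen <- sum(vapply(grp, function(b) sqrt(length(b)) * sqrt(sum(b^2)),
                          numeric(1)))
  loss + (1 - problem$alpha) * problem$lambda * group_pen +
    problem$alpha * problem$lambda * sum(abs(beta))
}

soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' Smallest penalty that zeroes all coefficients
#'
#' For `alpha = 1` this is the classic lasso bound
#' `max_j |x_j' y| / n`; for `alpha = 0` it is
#' `max_l ||X_l' y / n||_2 / sqrt(p_l)`; in between the per-group zero
#' condition is solved numerically (it is monotone in lambda).
#'
#' @param problem an [sgl_problem]; its `lambda` is ignored.
#' @return the critical lambda.
#' @export
sgl_lambda_max <- function(problem) {
  n <- length(problem$y)
  c_full <- drop(crossprod(problem$X, problem$y)) / n
  alpha <- problem$alpha
  idx <- split(seq_along(c_full), problem$groups)
  if (alpha == 1) return(max(abs(c_full)))
  if (alpha == 0)
    return(max(vapply(idx, function(j) sqrt(sum(c_full[j]^2)) / sqrt(length(j)),
                      numeric(1))))
  per_group <- vapply(idx, function(j) {
    cl <- c_full[j]
    pl <- length(j)
    f <- function(lam)
      sum(soft_threshold(cl, alpha * lam)^2) - ((1 - alpha) * lam * sqrt(pl))^2
    upper <- max(abs(cl)) / alpha
    if (upper <= 0) return(0)
    if (f(upper) > 0) return(upper)  # numerically flat group
    stats::uniroot(f, c(0, upper), tol = 1e-12)$root
  }, numeric(1))
  max(per_group)
}

#' Fit a sparse-group-lasso problem
#'
#' Block-coordinate descent over groups: each sweep first tests the group
#' soft-thresholding condition that zeroes a whole block, otherwise
#' minimizes over the block by proximal-gradient steps whose proximal
#' operator composes coordinate-wise soft-thresholding (the lasso part)
#' with group-norm shrinkage (the group part). The objective is
#' non-increasing across sweeps; convergence is declared when the largest
#' absolute coefficient change in a sweep falls below `tol`.
#'
#' @param problem an [sgl_problem].
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @param max_iter maximum number of outer sweeps.
#' @param beta0 optional warm start.
#' @return the coefficient vector, with attributes `converged`,
#'   `iterations` and `objective` (value at the returned iterate).
#' @export
fit_sgl <- function(problem, tol = 1e-7, max_iter = 10000L, beta0 = NULL) {
  stopifnot(inherits(problem, "sgl_problem"))
  if (tol <= 0) stop("tol must be > 0")
  X <- problem$X; y <- problem$y
  n <- length(y); p <- ncol(X)
  alpha <- problem$alpha; lambda <- problem$lambda
  idx <- split(seq_len(p), problem$groups)
  # Lipschitz constant of each block's gradient: ||X_l||_op^2 / n
  L <- vapply(idx, function(j) {
    s <- svd(X[, j, drop = FALSE], nu = 0, nv = 0)$d[1]
    max(s^2 / n, .Machine$double.eps)
  }, numeric(1))
  beta <- if (is.null(beta0)) numeric(p) else as.numeric(beta0)
  r <- y - drop(X %*% beta)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    max_change <- 0
    for (g in seq_along(idx)) {
      j <- idx[[g]]
      pl <- length(j)
      Xl <- X[, j, drop = FALSE]
      bl <- beta[j]
      rl <- r + drop(Xl %*% bl)              # partial residual excluding block g
      cl <- drop(crossprod(Xl, rl)) / n
      new_bl <-
        if (sqrt(sum(soft_threshold(cl, alpha * lambda)^2)) <=
            (1 - alpha) * lambda * sqrt(pl)) {
          numeric(pl)
        } else {
          b <- bl
          step <- 1 / L[g]
          for (inner in seq_len(1000L)) {
            grad <- -drop(crossprod(Xl, rl - drop(Xl %*% b))) / n
            u <- soft_threshold(b - step * grad, step * alpha * lambda)
            un <- sqrt(sum(u^2))
            shrink <- if (un > 0)
              max(0, 1 - step * (1 - alpha) * lambda * sqrt(pl) / un) else 0
            b_new <- shrink * u
            done <- max(abs(b_new - b)) < tol * 0.1
            b <- b_new
            if (done) break
          }
          b
        }
      if (length(new_bl) > 0 && any(new_bl != bl)) {
        r <- rl - drop(Xl %*% new_bl)
        max_change <- max(max_change, max(abs(new_bl - bl)))
        beta[j] <- new_bl
      }
    }
    if (max_change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fit_sgl did not converge in ", max_iter, " sweeps")
  structure(beta,
            converged = converged, iterations = it,
            objective = sgl_objective(beta, problem),
            names = colnames(X))
}

#' Select the penalty by cross-validation over genes
#'
#' The observational units of the per-sample regression are the signature
#' genes, so the folds partition genes. A log-spaced grid runs from the
#' critical penalty (all-zero fit) down three decades. Because the
#' held-out error curve is typically flat over a wide stretch of small
#' penalties, the literal arg-min is ill-conditioned with respect to the
#' fold assignment; the selected penalty is therefore the largest (most
#' regularized) grid value whose mean held-out squared error lies within
#' a small relative tolerance (`cv_rtol`) of the minimum. Deterministic
#' given `seed`.
#'
#' @param problem an [sgl_problem]; its `lambda` slot is ignored.
#' @param grid_size number of grid points (default 30).
#' @param folds number of folds over genes (default 5).
#' @param seed integer seed for the fold assignment.
#' @param cv_rtol relative tolerance above the minimum mean CV error
#'   within which the largest penalty is taken (default 0.01).
#' @return the selected lambda, with attributes `grid` and `cv_error`.
#' @export
select_lambda_cv <- function(problem, grid_size = 30L, folds = 5L, seed = 1L,
                             cv_rtol = 0.01) {
  stopifnot(inherits(problem, "sgl_problem"))
  n <- length(problem$y)
  if (folds < 2L || n < folds) stop("need n >= folds >= 2")
  if (stats::sd(problem$y) == 0) stop("constant response: nothing to fit")
  lam_max <- sgl_lambda_max(problem)
  if (lam_max <= 0) stop("degenerate problem: lambda_max is 0")
  grid <- exp(seq(log(lam_max), log(lam_max * 1e-3), length.out = grid_size))
  fold_of <- local({
    set.seed(seed)
    sample(rep_len(seq_len(folds), n))
  })
  err <- matrix(NA_real_, nrow = grid_size, ncol = folds)
  for (f in seq_len(folds)) {
    train <- fold_of != f
    sub <- sgl_problem(problem$y[train], problem$X[train, , drop = FALSE],
                       problem$group_labels, problem$alpha, 0)
    warm <- NULL
    for (i in seq_len(grid_size)) {
      sub$lambda <- grid[i]
      b <- fit_sgl(sub, tol = 1e-6, beta0 = warm)
      warm <- as.numeric(b)
      pred <- drop(problem$X[!train, , drop = FALSE] %*% warm)
      err[i, f] <- mean((problem$y[!train] - pred)^2)
    }
  }
  cv <- rowMeans(err)
  # grid is decreasing: the first index within tolerance is the largest lambda
  lam <- grid[min(which(cv <= min(cv) * (1 + cv_rtol)))]
  structure(lam, grid = grid, cv_error = cv)
}

#' Deconvolve bulk samples with the sparse group lasso
#'
#' One independent penalized regression per sample on the intersection of
#' expression and signature genes. Signature columns are standardized
#' internally (scaled to unit root-mean-square) for penalty selection and
#' fitting; coefficients are returned on the original scale. Estimates are
#' the raw regression coefficients and may be negative unless
#' `nonneg = TRUE` clamps them at zero.
#'
#' @param expr an [expression_matrix].
#' @param sig a [signature_matrix].
#' @param alpha mixing weight, default `0.5`.
#' @param lambda `"cv"` (per-sample cross-validation; for cohorts above 25
#'   samples the penalty is cross-validated on 10 evenly spaced samples and
#'   the median reused) or a numeric penalty applied to every sample on the
#'   standardized scale.
#' @param nonneg clamp negative coefficients at zero (default `FALSE`).
#' @param min_overlap minimum gene overlap required (default 30).
#' @param seed seed for cross-validation folds.
#' @param tol,max_iter solver controls, see [fit_sgl()].
#' @return an [estimate_table()] with `tool_name = "SGL"`.
#' @export
deconvolve_sgl <- function(expr, sig, alpha = 0.5, lambda = "cv",
                           nonneg = FALSE, min_overlap = 30L, seed = 1L,
                           tol = 1e-7, max_iter = 10000L) {
  stopifnot(inherits(sig, "signature_matrix"))
  genes <- intersect(rownames(expr), rownames(sig$values))
  if (length(genes) < min_overlap)
    stop("only ", length(genes), " signature genes overlap expression (need >= ",
         min_overlap, ")")
  X <- sig$values[genes, , drop = FALSE]
  scale_j <- sqrt(colMeans(X^2))
  scale_j[scale_j == 0] <- 1
  Xs <- sweep(X, 2, scale_j, "/")
  E <- unclass(expr)[genes, , drop = FALSE]
  ns <- ncol(E)
  lambdas <- rep(NA_real_, ns)
  if (is.numeric(lambda)) {
    lambdas <- rep_len(lambda, ns)
  } else if (identical(lambda, "cv")) {
    cv_samples <- if (ns <= 25L) seq_len(ns) else
      unique(round(seq(1, ns, length.out = 10L)))
    sel <- vapply(cv_samples, function(i) {
      y <- E[, i]
      if (stats::sd(y) == 0) return(NA_real_)
      as.numeric(select_lambda_cv(sgl_problem(y, Xs, sig$groups, alpha, 0),
                                  seed = seed))
    }, numeric(1))
    if (all(is.na(sel))) stop("all samples constant: nothing to fit")
    if (ns <= 25L) {
      lambdas <- sel
      lambdas[is.na(lambdas)] <- stats::median(sel, na.rm = TRUE)
    } else {
      lambdas <- rep(stats::median(sel, na.rm = TRUE), ns)
    }
  } else stop("lambda must be \"cv\" or numeric")
  est <- matrix(0, nrow = ns, ncol = ncol(X),
                dimnames = list(colnames(E), colnames(X)))
  for (i in seq_len(ns)) {
    y <- E[, i]
    if (all(y == 0)) next
    pr <- sgl_problem(y, Xs, sig$groups, alpha, lambdas[i])
    b <- as.numeric(fit_sgl(pr, tol = tol, max_iter = max_iter)) / scale_j
    if (nonneg) b <- pmax(b, 0)
    est[i, ] <- b
  }
  estimate_table(est, tool_name = "SGL")
}
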