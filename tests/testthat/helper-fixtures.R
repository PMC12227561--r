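# Small fixture builders shared across test files.

write_tsv_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_expression <- function(n_genes = 10, n_samples = 4, seed = 1) {
  set.seed(seed)
  expression_matrix(matrix(stats::runif(n_genes * n_samples, 0, 10),
                           n_genes, n_samples,
                           dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                           sprintf("s%02d", seq_len(n_samples)))))
}

toy_signature <- function(n_genes = 40, n_types = 4, seed = 2) {
  set.seed(seed)
  v <- matrix(stats::rexp(n_genes * n_types), n_genes, n_types,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              paste0("ct", seq_len(n_types))))
  signature_matrix(v, stats::setNames(rep(c("A", "B"), length.out = n_types),
                                      colnames(v)))
}

toy_estimates <- function(tool, values) {
  estimate_table(values, tool_name = tool)
}

# exhaustive sign-pattern oracle for small NNLS problems
nnls_oracle <- function(X, y) {
  p <- ncol(X)
  best <- list(obj = sum(y^2), x = numeric(p))
  for (k in seq_len(2^p) - 1L) {
    active <- which(bitwAnd(k, 2^(seq_len(p) - 1L)) > 0)
    if (length(active) == 0) next
    Xa <- X[, active, drop = FALSE]
    b <- tryCatch(solve(crossprod(Xa), crossprod(Xa, y)),
                  error = function(e) NULL)
    if (is.null(b) || any(b < 0)) next
    r <- y - Xa %*% b
    obj <- sum(r^2)
    if (obj < best$obj) {
      x <- numeric(p); x[active] <- b
      best <- list(obj = obj, x = x)
    }
  }
  best
}

# explicit running-sum ssGSEA oracle for one sample
ssgsea_oracle <- function(values, set_members, tau) {
  r <- rank(values, ties.method = "average")
  ord <- order(-r, seq_along(r))
  running <- 0; total <- 0
  in_set <- names(values)[ord] %in% set_members
  w <- r[ord]^tau
  w_in_total <- sum(w[in_set])
  n_out <- sum(!in_set)
  for (i in seq_along(ord)) {
    if (in_set[i]) running <- running + w[i] / w_in_total
    else running <- running - 1 / n_out
    total <- total + running
  }
  unname(total)
}

# direct Welch statistic and p-value
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}
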