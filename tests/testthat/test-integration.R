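test_that("standardization gives exact z-scores under the sample-sd convention", {
  est <- toy_estimates("t1", matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
    dimnames = list(c("a", "b", "c"), c("ct1", "flat"))))
  expect_warning(z <- standardize_estimates(est), "zero-variance")
  expect_equal(unname(unclass(z)[, "ct1"]), c(-1, 0, 1))
  expect_false("flat" %in% colnames(z))
  expect_error(standardize_estimates(toy_estimates("t1",
    matrix(1, 1, 1, dimnames = list("a", "x")))), "2 samples")
})

test_that("every retained standardized column has mean 0 and sd 1", {
  set.seed(12)
  est <- toy_estimates("t1", matrix(rnorm(60, 5, 3), 10, 6,
    dimnames = list(sprintf("s%02d", 1:10), paste0("ct", 1:6))))
  z <- unclass(standardize_estimates(est))
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-10))
})

test_that("harmonization renames, averages within-tool duplicates, flags unmapped", {
  map <- data.frame(tool = c("A", "A", "A", "B"),
                    tool_celltype = c("T cells CD8", "CD8 T cells", "Tregs",
                                      "CD8 T cells"),
                    canonical = c("CD8_T", "CD8_T", "T_regs", "CD8_T"),
                    lineage = "lymphoid", class = "cell_type")
  class(map) <- c("celltype_mapping", "data.frame")
  za <- structure(matrix(c(1, -1, 3, 1, 0, 0), 2, 3,
                         dimnames = list(c("s1", "s2"),
                                         c("T cells CD8", "CD8 T cells", "Unknown"))),
                  tool_name = "A",
                  class = c("standardized_table", "matrix", "array"))
  zb <- structure(matrix(c(2, -2), 2, 1,
                         dimnames = list(c("s1", "s2"), "CD8 T cells")),
                  tool_name = "B",
                  class = c("standardized_table", "matrix", "array"))
  expect_warning(al <- harmonize(list(za, zb), map), "Unknown")
  expect_equal(colnames(al[[1]]), "CD8_T")
  expect_equal(unname(unclass(al[[1]])[, "CD8_T"]), c(2, 0))  # within-tool mean
  expect_equal(colnames(attr(al[[1]], "unmapped")), "Unknown")
  expect_equal(colnames(al[[2]]), "CD8_T")

  zc <- structure(zb, tool_name = "C")
  expect_error(harmonize(list(zc), map), "no mapping entries")
})

make_std <- function(tool, v) {
  structure(v, tool_name = tool,
            class = c("standardized_table", "matrix", "array"))
}

test_that("iScores are tool means with identity, cancellation and averaging", {
  samples <- c("s1", "s2", "s3")
  z1 <- make_std("t1", matrix(c(0.5, 1, -1), 3, 1,
                              dimnames = list(samples, "CD8_T")))
  # single tool: identity
  i1 <- compute_iscores(list(z1))
  expect_equal(unclass(i1), unclass(z1), ignore_attr = TRUE)
  expect_equal(attr(i1, "provenance")$CD8_T, "t1")
  # z and -z cancel
  z2 <- make_std("t2", -unclass(z1))
  expect_true(all(unclass(compute_iscores(list(z1, z2))) == 0))
  # three tools average
  z3 <- make_std("t3", matrix(c(1.5, 0, 0), 3, 1,
                              dimnames = list(samples, "CD8_T")))
  z4 <- make_std("t4", matrix(c(1.0, 0, 0), 3, 1,
                              dimnames = list(samples, "CD8_T")))
  z5 <- make_std("t5", matrix(c(0.5, 0, 0), 3, 1,
                              dimnames = list(samples, "CD8_T")))
  expect_equal(unclass(compute_iscores(list(z3, z4, z5)))["s1", "CD8_T"], 1.0)
  # mismatched sample sets are rejected with the difference listed
  z6 <- make_std("t6", matrix(1, 1, 1, dimnames = list("s9", "CD8_T")))
  expect_error(compute_iscores(list(z1, z6)), "s9")
})

test_that("integration is order-invariant and duplicate-tool invariant", {
  set.seed(8)
  samples <- sprintf("s%02d", 1:6)
  zs <- lapply(1:3, function(i)
    make_std(paste0("t", i),
             matrix(rnorm(12), 6, 2, dimnames = list(samples, c("A", "B")))))
  a <- compute_iscores(zs)
  b <- compute_iscores(rev(zs))
  expect_equal(unclass(a), unclass(b)[rownames(a), colnames(a)],
               ignore_attr = TRUE)
  # duplicating an existing tool's z-scores changes nothing
  dup <- make_std("copy", unclass(zs[[2]]))
  mean3 <- unclass(compute_iscores(zs))
  # mean over {z1,z2,z2,z3} != mean over {z1,z2,z3} in general, but adding an
  # exact duplicate of the per-celltype mean leaves it unchanged:
  zmean <- make_std("mean", unclass(a))
  expect_equal(unclass(compute_iscores(c(zs, list(zmean)))), mean3,
               ignore_attr = TRUE)
})

test_that("leukocyte and stromal aggregates follow lineage flags", {
  map <- data.frame(
    tool = "t1",
    tool_celltype = c("CD8", "Mac", "Fibroblasts", "Endothelial_cells",
                      "Pericytes", "Adipocytes", "Hypoxia"),
    canonical = c("CD8", "Mac", "Fibroblasts", "Endothelial_cells",
                  "Pericytes", "Adipocytes", "Hypoxia"),
    lineage = c("lymphoid", "myeloid", "stromal", "stromal", "stromal",
                "stromal", "other"),
    class = c(rep("cell_type", 6), "process"))
  class(map) <- c("celltype_mapping", "data.frame")
  v <- matrix(c(2, 0,   1, 0,   1, 0,  -1, 0,   0.5, 0,  -0.5, 0,  9, 9),
              2, 7, dimnames = list(c("s1", "s2"),
                                    map$tool_celltype))
  z <- make_std("t1", v)
  agg <- aggregate_iscores(list(z), map)
  expect_equal(agg$Leukocyte_iScore[1], mean(c(2, 1)))     # CD8 + Mac
  expect_equal(agg$Stromal_iScore[1], 0)                   # (1,-1,0.5,-0.5)
  # the process column contributes to neither aggregate
  expect_false(any(agg$Leukocyte_iScore > 2))

  # stromal-only data: leukocyte aggregate undefined and flagged
  z_st <- make_std("t1", v[, 3:6])
  expect_warning(agg2 <- aggregate_iscores(list(z_st), map), "Leukocyte")
  expect_true(all(is.na(agg2$Leukocyte_iScore)))

  # single immune cell type from a single tool: aggregate equals that column
  z_cd8 <- make_std("t1", v[, "CD8", drop = FALSE])
  agg3 <- suppressWarnings(aggregate_iscores(list(z_cd8), map))
  expect_equal(agg3$Leukocyte_iScore, unname(v[, "CD8"]))
})

test_that("pearson correlation matches hand values and a summation oracle", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_correlation(c(1, 2, 3), c(6, 4, 2)), -1.0)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(r <- pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r))
  set.seed(55)
  for (i in 1:100) {
    x <- rnorm(10); y <- rnorm(10)
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson_correlation(x, y), oracle, tolerance = 1e-12)
  }
})

test_that("method comparison recovers planted correlation ranking", {
  set.seed(7)
  n <- 200
  truth <- matrix(runif(n * 2), n, 2,
                  dimnames = list(sprintf("s%03d", 1:n), c("A", "B")))
  noisy <- function(noise) {
    v <- truth + matrix(rnorm(n * 2, sd = noise), n, 2)
    dimnames(v) <- dimnames(truth)
    v
  }
  ests <- list(iScore = noisy(0.1), m2 = noisy(0.35), m3 = noisy(0.9))
  cmp <- method_comparison(ests, truth)
  for (ct in c("A", "B")) {
    expect_gt(cmp$correlations["iScore", ct], cmp$correlations["m2", ct])
    expect_gt(cmp$correlations["m2", ct], cmp$correlations["m3", ct])
  }
  expect_equal(cmp$fraction_best_or_tied, 1.0)
  # a method compared with itself is always best-or-tied
  solo <- method_comparison(list(iScore = ests$iScore), truth)
  expect_equal(solo$fraction_best_or_tied, 1.0)
  # exact ties count as best-or-tied
  tied <- method_comparison(list(iScore = ests$m2, rival = ests$m2), truth)
  expect_equal(tied$fraction_best_or_tied, 1.0)
})
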