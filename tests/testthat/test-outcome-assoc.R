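test_that("tertile groups split exact thirds with ties going low", {
  s9 <- stats::setNames(1:9, paste0("s", 1:9))
  g <- tertile_groups(s9)
  expect_equal(unname(table(g)), array(c(3L, 3L, 3L)))
  expect_true(all(g[paste0("s", 1:3)] == "LOW"))
  expect_true(all(g[paste0("s", 7:9)] == "HIGH"))
  # boundary ties resolve deterministically and reproducibly
  tied <- stats::setNames(c(1, 1, 1, 2, 3, 3, 3), paste0("s", 1:7))
  expect_identical(tertile_groups(tied), tertile_groups(tied))
  q <- quantile(tied, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  expect_true(all(tertile_groups(tied)[tied <= q[1]] == "LOW"))
  expect_error(tertile_groups(c(a = 1, b = 1, c = 1)), "identical")
  expect_error(tertile_groups(c(a = 1, b = 2)), ">= 3")
})

test_that("Cox recovery: planted hazard ratio is estimated within tolerance", {
  sim <- simulate_survival_strata(2000, hr = 0.7, event_rate = 0.6, seed = 12)
  res <- cox_stratified(sim$clinical, sim$strata)
  expect_false(res$inestimable)
  expect_gt(res$hr, 0.6)
  expect_lt(res$hr, 0.82)
  expect_gt(res$n_events / res$n, 0.4)
})

test_that("Cox null coverage: the CI covers 1 in at least 90% of replicates", {
  covered <- 0L
  n_rep <- 100L
  for (rep in seq_len(n_rep)) {
    sim <- simulate_survival_strata(250, hr = 1.0, event_rate = 0.6,
                                    seed = 1000 + rep)
    res <- cox_stratified(sim$clinical, sim$strata,
                          covariates = c("age", "gender"))
    if (!res$inestimable && res$ci_low <= 1 && res$ci_high >= 1)
      covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.90)
})

test_that("swapping stratum labels inverts the hazard ratio", {
  sim <- simulate_survival_strata(800, hr = 0.6, seed = 77)
  res <- cox_stratified(sim$clinical, sim$strata,
                        covariates = character())
  flipped <- sim$strata
  levels(flipped) <- c("HIGH", "EXCLUDED", "LOW")
  res2 <- cox_stratified(sim$clinical, flipped, covariates = character())
  expect_equal(res2$hr, 1 / res$hr, tolerance = 1e-6)
})

test_that("per-cancer Cox corrects across cancers and flags inestimable strata", {
  sim <- simulate_survival_strata(1200, hr = 0.7, n_cancers = 4, seed = 5)
  res <- cox_stratified(sim$clinical, sim$strata, scope = "per-cancer",
                        covariates = c("age", "gender"))
  expect_equal(nrow(res), 4L)
  ok <- !is.na(res$p)
  expect_equal(res$q[ok], bh_fdr(res$p[ok]))
  expect_true(all(res$q >= res$p, na.rm = TRUE))
})

test_that("additive two-score model recovers both planted effects and is symmetric", {
  set.seed(41)
  n <- 3000
  ids <- sprintf("s%05d", 1:n)
  sa <- stats::setNames(rnorm(n), ids); sb <- stats::setNames(rnorm(n), ids)
  ga <- tertile_groups(sa); gb <- tertile_groups(sb)
  loghr <- log(0.6) * (ga == "HIGH") + log(1.5) * (gb == "HIGH")
  t_event <- rexp(n, 0.01 * exp(loghr))
  t_cens <- runif(n, 0, quantile(t_event, 0.95))
  clin <- data.frame(sample_id = ids, time = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens))
  class(clin) <- c("clinical_table", "data.frame")
  res <- combo_cox(clin, ga, gb)
  hi_lo <- res[res$group_a == "HIGH" & res$group_b == "LOW", ]
  lo_hi <- res[res$group_a == "LOW" & res$group_b == "HIGH", ]
  expect_lt(abs(log(hi_lo$hr) - log(0.6)), 0.2)
  expect_lt(abs(log(lo_hi$hr) - log(1.5)), 0.2)
  # order symmetry
  res_swapped <- combo_cox(clin, gb, ga)
  expect_equal(sort(res_swapped$hr), sort(res$hr), tolerance = 1e-10)
})

test_that("combo model under the null covers HR 1 in most replicates", {
  covered <- 0L
  n_rep <- 30L
  for (rep in seq_len(n_rep)) {
    set.seed(3000 + rep)
    n <- 400
    ids <- sprintf("s%04d", 1:n)
    ga <- tertile_groups(stats::setNames(rnorm(n), ids))
    gb <- tertile_groups(stats::setNames(rnorm(n), ids))
    t_event <- rexp(n, 0.01)
    t_cens <- runif(n, 0, quantile(t_event, 0.9))
    clin <- data.frame(sample_id = ids, time = pmin(t_event, t_cens),
                       event = as.integer(t_event <= t_cens))
    class(clin) <- c("clinical_table", "data.frame")
    res <- combo_cox(clin, ga, gb)
    row <- res[res$group_a == "HIGH" & res$group_b == "LOW", ]
    if (!row$inestimable && row$ci_low <= 1 && row$ci_high >= 1)
      covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.9)
})

simulate_interaction <- function(n, int_hr, seed) {
  set.seed(seed)
  ids <- sprintf("s%04d", 1:n)
  scores <- stats::setNames(rnorm(n), ids)
  strata <- tertile_groups(scores)
  subtype <- sample(c("LumA", "Her2", "Basal"), n, replace = TRUE,
                    prob = c(0.6, 0.2, 0.2))
  loghr <- ifelse(strata == "HIGH" & subtype == "Her2", log(int_hr), 0)
  t_event <- rexp(n, 0.01 * exp(loghr))
  t_cens <- runif(n, 0, quantile(t_event, 0.95))
  clin <- data.frame(sample_id = ids, time = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens), subtype = subtype)
  class(clin) <- c("clinical_table", "data.frame")
  list(clinical = clin, strata = strata)
}

test_that("interaction model recovers a subtype-specific protective effect", {
  sim <- simulate_interaction(600, int_hr = 0.25, seed = 52)
  res <- interaction_cox(sim$clinical, sim$strata, "LumA")
  expect_false("LumA" %in% res$subtype)
  her2 <- res[res$subtype == "Her2", ]
  expect_false(her2$inestimable)
  expect_gt(her2$hr, 0.12)
  expect_lt(her2$hr, 0.5)
})

test_that("interaction CIs cover 1 under the null in most replicates", {
  covered <- 0L; total <- 0L
  for (rep in 1:25) {
    sim <- simulate_interaction(400, int_hr = 1.0, seed = 6000 + rep)
    res <- interaction_cox(sim$clinical, sim$strata, "LumA")
    for (i in seq_len(nrow(res))) {
      if (res$inestimable[i]) next
      total <- total + 1L
      if (res$ci_low[i] <= 1 && res$ci_high[i] >= 1) covered <- covered + 1L
    }
  }
  expect_gte(covered / total, 0.9)
})

test_that("driver association recovers a planted coefficient with q < 0.1", {
  sim <- simulate_driver_dataset(2000, beta_d = 0.5, n_mutated = 200, seed = 8)
  res <- driver_association(sim$iscores, sim$mutations, sim$cancer_of)
  expect_equal(nrow(res), 1L)
  expect_gt(res$coef, 0.35)
  expect_lt(res$coef, 0.65)
  expect_lt(res$q, 0.1)
  expect_true(res$significant)
})

test_that("driver coefficients are exact on noiseless data and location-invariant", {
  sim <- simulate_driver_dataset(500, beta_d = 0.7, n_mutated = 60,
                                 sigma = 0, seed = 10)
  res <- suppressWarnings(driver_association(sim$iscores, sim$mutations, sim$cancer_of))
  expect_equal(res$coef, 0.7, tolerance = 1e-8)
  shifted <- sim$iscores + 5
  res2 <- suppressWarnings(driver_association(shifted, sim$mutations, sim$cancer_of))
  expect_equal(res2$coef, res$coef, tolerance = 1e-10)
})

test_that("genes at or below the mutation floor are excluded", {
  sim <- simulate_driver_dataset(300, beta_d = 1, n_mutated = 5, seed = 2)
  expect_message(
    res <- driver_association(sim$iscores, sim$mutations, sim$cancer_of),
    "excluded")
  expect_equal(nrow(res), 0L)
})

test_that("null driver genes are rarely flagged at q < 0.1", {
  set.seed(88)
  n <- 500
  ids <- sprintf("s%04d", 1:n)
  cancer <- stats::setNames(sample(paste0("C", 1:4), n, replace = TRUE), ids)
  iscores <- matrix(rnorm(n), ncol = 1, dimnames = list(ids, "ct1"))
  genes <- paste0("G", 1:100)
  mut <- do.call(rbind, lapply(genes, function(g)
    data.frame(sample_id = sample(ids, 30), gene = g, variant = "p.X")))
  class(mut) <- c("mutation_table", "data.frame")
  res <- driver_association(iscores, mut, cancer, genes = genes)
  expect_lte(mean(res$q < 0.1), 0.1)
})

test_that("MSI/POLE joint model recovers effects and flags degeneracies", {
  set.seed(34)
  n <- 2000
  ids <- sprintf("s%05d", 1:n)
  M <- rbinom(n, 1, 0.10); P <- rbinom(n, 1, 0.05)
  y <- 1.0 * M + 0 * P + rnorm(n)
  iscores <- matrix(y, ncol = 1, dimnames = list(ids, "ct1"))
  flags <- data.frame(sample_id = ids, msi_h = M, pole = P)
  res <- msi_pole_association(iscores, flags)
  bm <- res[res$term == "msi_h", ]
  bp <- res[res$term == "pole", ]
  expect_gt(bm$coef, 0.8); expect_lt(bm$coef, 1.2)
  expect_true(bp$coef - 1.96 * bp$se <= 0 && bp$coef + 1.96 * bp$se >= 0)

  # perfectly collinear flags are flagged, not silently fit
  flags2 <- data.frame(sample_id = ids, msi_h = M, pole = M)
  res2 <- msi_pole_association(iscores, flags2)
  expect_true(all(res2$inestimable))

  # constant flag inestimable
  flags3 <- data.frame(sample_id = ids, msi_h = M, pole = 0)
  res3 <- msi_pole_association(iscores, flags3)
  expect_true(all(res3$inestimable[res3$term == "pole"]))
  expect_false(any(res3$inestimable[res3$term == "msi_h"]))
})

test_that("variant Welch test matches the closed form and enforces carriers floor", {
  ids <- sprintf("s%02d", 1:20)
  scores <- stats::setNames(c(1, 2, 3, 4, 5, 2, 4, 6, rnorm(12)), ids)
  mut <- data.frame(
    sample_id = c(ids[1:6], ids[7:9]),
    gene = "FGFR3",
    variant = c(rep("p.S249C", 6), rep("p.Y375C", 3)))
  class(mut) <- c("mutation_table", "data.frame")
  res <- variant_welch(scores, mut, "FGFR3", "p.S249C")
  oracle <- welch_oracle(scores[ids[1:6]], scores[ids[10:20]])
  expect_equal(res$t, oracle$t, tolerance = 1e-10)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
  # carriers of other variants are excluded from the comparison group
  expect_equal(res$n_wildtype, 11L)
  expect_error(variant_welch(scores, mut, "FGFR3", "p.Y375C"), "need >")
})

test_that("identical groups give t = 0, p = 1; separated groups are significant", {
  ids <- sprintf("s%02d", 1:12)
  scores <- stats::setNames(c(1, 2, 3, 1, 2, 3, rep(c(1, 2, 3), 2)), ids)
  mut <- data.frame(sample_id = ids[1:6], gene = "G", variant = "v")
  class(mut) <- c("mutation_table", "data.frame")
  res <- variant_welch(scores, mut, "G", "v", min_carriers = 2)
  expect_equal(res$t, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)

  set.seed(1)
  scores2 <- stats::setNames(c(rep(0, 6), rep(1, 6)) + rnorm(12, sd = 1e-3), ids)
  res2 <- variant_welch(scores2, mut, "G", "v", min_carriers = 2)
  expect_lt(res2$p, 0.01)
})

test_that("TMB quartile comparison forms exact groups and controls the null", {
  ids <- sprintf("s%02d", 1:8)
  iscores <- matrix(rnorm(8), ncol = 1, dimnames = list(ids, "ct1"))
  counts <- stats::setNames(1:8, ids)
  # 8 distinct counts -> 2 per quartile group
  res <- tmb_group_compare(iscores, counts)
  expect_equal(nrow(res), 1L)

  set.seed(61)
  flagged <- 0L
  for (rep in 1:100) {
    n <- 60
    ids <- sprintf("s%03d", 1:n)
    v <- matrix(rnorm(n * 5), n, 5, dimnames = list(ids, paste0("ct", 1:5)))
    cnt <- stats::setNames(rpois(n, 50), ids)
    out <- tmb_group_compare(v, cnt)
    flagged <- flagged + sum(out$significant)
  }
  expect_lte(flagged / (100 * 5), 0.05)
})

test_that("a planted TMB shift is detected for the right cell type", {
  set.seed(71)
  n <- 400
  ids <- sprintf("s%03d", 1:n)
  cnt <- stats::setNames(rpois(n, 100), ids)
  v <- matrix(rnorm(n * 4), n, 4, dimnames = list(ids, paste0("ct", 1:4)))
  hi <- cnt > quantile(cnt, 0.75)
  v[hi, "ct2"] <- v[hi, "ct2"] + 1
  res <- tmb_group_compare(v, cnt)
  expect_true(res$significant[res$celltype == "ct2"])
  res_mw <- tmb_group_compare(v, cnt, test = "mannwhitney")
  expect_true(res_mw$significant[res_mw$celltype == "ct2"])
})

test_that("BH q-values match the step-up formula and the reference oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(99)
  for (rep in 1:1000) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-14)
    expect_true(all(diff(q[order(p)]) > -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
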