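#' Simulate survival data with a known hazard ratio between strata
#'
#' Generates a per-sample score, tertile-stratifies it, and draws
#' exponential survival times whose hazard is multiplied by `hr` for the
#' HIGH stratum (reference LOW; the EXCLUDED middle third keeps hazard 1).
#' Censoring is uniform, calibrated to the requested event rate. Optional
#' balanced covariates (cancer type, localization, age, gender) are
#' generated with no effect on hazard unless `covariate_loghr` is set.
#'
#' @param n number of samples.
#' @param hr hazard ratio of HIGH vs LOW.
#' @param event_rate approximate fraction of observed events.
#' @param n_cancers,n_localizations numbers of balanced categorical levels.
#' @param covariate_loghr log-hazard effect of the age covariate, default 0.
#' @param seed integer seed.
#' @return list with `clinical` (a `clinical_table`-shaped data frame),
#'   `scores` (named vector) and `strata`.
#' @export
simulate_survival_strata <- function(n, hr = 0.7, event_rate = 0.6,
                                     n_cancers = 4L, n_localizations = 3L,
                                     covariate_loghr = 0, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("s%05d", seq_len(n))
  scores <- stats::setNames(stats::rnorm(n), ids)
  strata <- tertile_groups(scores)
  age <- stats::rnorm(n, 60, 10)
  hazard <- 0.01 * ifelse(strata == "HIGH", hr, 1) *
    exp(covariate_loghr * (age - 60) / 10)
  t_event <- stats::rexp(n, rate = hazard)
  # uniform censoring window tuned to the target event fraction
  cmax <- stats::quantile(t_event, min(1, event_rate * 2))
  t_cens <- stats::runif(n, 0, cmax)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  clinical <- data.frame(
    sample_id = ids, time = time, event = event,
    cancer_type = sample(paste0("C", seq_len(n_cancers)), n, replace = TRUE),
    localization = sample(paste0("L", seq_len(n_localizations)), n, replace = TRUE),
    age = age,
    gender = sample(c("F", "M"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  class(clinical) <- c("clinical_table", "data.frame")
  list(clinical = clinical, scores = scores, strata = strata)
}

#' Simulate a driver-mutation effect on iScores
#'
#' Generates a cohort with cancer-type offsets, a Bernoulli driver
#' mutation indicator and one cell type's iScore following
#' `iScore = beta_d * D + cancer offset + N(0, sigma)`, plus the matching
#' mutation table.
#'
#' @param n cohort size.
#' @param beta_d additive effect of mutation on the iScore.
#' @param n_mutated number of mutated samples.
#' @param n_cancers cancer types (balanced), each with its own offset.
#' @param sigma residual standard deviation, default 1.
#' @param gene gene symbol used in the mutation table.
#' @param seed integer seed.
#' @return list with `iscores` (n x 1 matrix), `mutations`
#'   (mutation-table-shaped data frame), `cancer_of` (named vector), `D`.
#' @export
simulate_driver_dataset <- function(n, beta_d = 0.5, n_mutated = 200L,
                                    n_cancers = 5L, sigma = 1,
                                    gene = "GENE1", seed = 8L) {
  set.seed(seed)
  ids <- sprintf("s%05d", seq_len(n))
  cancer <- stats::setNames(sample(paste0("C", seq_len(n_cancers)), n,
                                   replace = TRUE), ids)
  offsets <- stats::setNames(stats::rnorm(n_cancers, 0, 0.5),
                             paste0("C", seq_len(n_cancers)))
  D <- stats::setNames(integer(n), ids)
  D[sample(n, n_mutated)] <- 1L
  y <- beta_d * D + offsets[cancer] + stats::rnorm(n, 0, sigma)
  iscores <- matrix(y, ncol = 1, dimnames = list(ids, "celltype1"))
  mutations <- data.frame(sample_id = ids[D == 1L], gene = gene,
                          variant = "p.X1", stringsAsFactors = FALSE)
  class(mutations) <- c("mutation_table", "data.frame")
  list(iscores = iscores, mutations = mutations, cancer_of = cancer, D = D)
}
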