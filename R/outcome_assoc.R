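#' Tertile stratification of a score
#'
#' HIGH is the top third and LOW the bottom third of the score's global
#' distribution (type-7 empirical quantiles at 1/3 and 2/3); the middle
#' third is EXCLUDED. Values tied with a boundary go to the lower stratum,
#' so the labeling is deterministic. LOW is the reference group in every
#' downstream model.
#'
#' @param scores named numeric vector (one score per sample).
#' @return named factor with levels `LOW`, `EXCLUDED`, `HIGH`.
#' @export
tertile_groups <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 3L) stop("need >= 3 samples")
  if (stats::sd(scores) == 0) stop("all scores identical: no strata")
  q <- stats::quantile(scores, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  lab <- ifelse(scores <= q[1], "LOW",
                ifelse(scores <= q[2], "EXCLUDED", "HIGH"))
  factor(stats::setNames(lab, names(scores)),
         levels = c("LOW", "EXCLUDED", "HIGH"))
}

strata_frame <- function(clinical, strata) {
  df <- as.data.frame(clinical)
  df$stratum <- strata[df$sample_id]
  df <- df[!is.na(df$stratum) & df$stratum != "EXCLUDED", , drop = FALSE]
  df$stratum <- factor(as.character(df$stratum), levels = c("LOW", "HIGH"))
  df
}

cox_covariate_terms <- function(df, covariates) {
  usable <- covariates[covariates %in% colnames(df)]
  keep <- stats::complete.cases(df[usable])
  if (any(!keep))
    message(sum(!keep), " sample(s) dropped for missing covariates")
  list(df = df[keep, , drop = FALSE],
       terms = usable[vapply(usable, function(cv)
         length(unique(df[[cv]][keep])) > 1L, logical(1))],
       n_dropped = sum(!keep))
}

#' Cox proportional-hazards model of HIGH vs LOW strata
#'
#' Fits HIGH-versus-LOW (reference LOW) Cox models with Efron tie
#' handling, adjusted for the requested covariates; missing covariate rows
#' are listwise-deleted with the count recorded. Pan-cancer fits include
#' `cancer_type` as a covariate; per-cancer fits run one model per cancer
#' and correct p-values across cancers by Benjamini-Hochberg
#' (significance convention q < 0.1).
#'
#' @param clinical a `clinical_table`.
#' @param strata stratum labels from [tertile_groups()].
#' @param covariates covariate column names; default
#'   `c("cancer_type", "localization", "age", "gender")`, with `stage`
#'   added where available. Missing columns are skipped.
#' @param scope `"pan-cancer"` (one model) or `"per-cancer"` (one model
#'   per `cancer_type` plus FDR across cancers).
#' @return data frame with `scope`, `hr`, `se`, `ci_low`, `ci_high`, `p`,
#'   (`q` for per-cancer), `n`, `n_events`, `inestimable`.
#' @export
cox_stratified <- function(clinical, strata,
                           covariates = c("cancer_type", "localization",
                                          "age", "gender", "stage"),
                           scope = c("pan-cancer", "per-cancer")) {
  scope <- match.arg(scope)
  df <- strata_frame(clinical, strata)
  fit_one <- function(sub, covs) {
    res <- data.frame(hr = NA_real_, se = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = NA_real_,
                      n = nrow(sub), n_events = sum(sub$event),
                      inestimable = FALSE)
    if (!all(c("LOW", "HIGH") %in% sub$stratum) ||
        sum(sub$event[sub$stratum == "LOW"]) == 0 ||
        sum(sub$event[sub$stratum == "HIGH"]) == 0) {
      res$inestimable <- TRUE
      return(res)
    }
    prep <- cox_covariate_terms(sub, covs)
    sub <- prep$df
    res$n <- nrow(sub); res$n_events <- sum(sub$event)
    rhs <- paste(c("stratum", prep$terms), collapse = " + ")
    fit <- tryCatch(
      survival::coxph(stats::as.formula(paste("survival::Surv(time, event) ~", rhs)),
                      data = sub, ties = "efron"),
      error = function(e) NULL)
    if (is.null(fit) || is.na(stats::coef(fit)["stratumHIGH"])) {
      res$inestimable <- TRUE
      return(res)
    }
    sm <- summary(fit)
    res$hr <- unname(sm$conf.int["stratumHIGH", "exp(coef)"])
    res$se <- unname(sm$coefficients["stratumHIGH", "se(coef)"])
    res$ci_low <- unname(sm$conf.int["stratumHIGH", "lower .95"])
    res$ci_high <- unname(sm$conf.int["stratumHIGH", "upper .95"])
    res$p <- unname(sm$coefficients["stratumHIGH", "Pr(>|z|)"])
    res
  }
  if (scope == "pan-cancer") {
    out <- cbind(data.frame(scope = "pan-cancer"), fit_one(df, covariates))
  } else {
    if (!"cancer_type" %in% colnames(df))
      stop("per-cancer scope needs a cancer_type column")
    covs <- setdiff(covariates, "cancer_type")
    pieces <- lapply(split(df, df$cancer_type), fit_one, covs = covs)
    out <- cbind(data.frame(scope = names(pieces)), do.call(rbind, pieces))
    out$q <- NA_real_
    ok <- !is.na(out$p)
    out$q[ok] <- bh_fdr(out$p[ok])
  }
  rownames(out) <- NULL
  out
}

#' Additive Cox model of two stratified scores
#'
#' Fits `Surv ~ strata_a + strata_b` on samples in the HIGH or LOW stratum
#' of both scores and reports each non-reference joint group's hazard
#' ratio against the double-LOW reference (off-diagonal HRs combine the
#' two coefficients, with the delta-method standard error).
#'
#' @param clinical a `clinical_table`.
#' @param strata_a,strata_b stratum labels from [tertile_groups()].
#' @param covariates optional covariate columns, as in [cox_stratified()].
#' @return data frame with one row per non-reference joint group:
#'   `group_a`, `group_b`, `hr`, `ci_low`, `ci_high`, `n`, `inestimable`.
#' @export
combo_cox <- function(clinical, strata_a, strata_b, covariates = character()) {
  df <- as.data.frame(clinical)
  df$sa <- strata_a[df$sample_id]
  df$sb <- strata_b[df$sample_id]
  df <- df[!is.na(df$sa) & !is.na(df$sb) &
             df$sa != "EXCLUDED" & df$sb != "EXCLUDED", , drop = FALSE]
  df$sa <- factor(as.character(df$sa), levels = c("LOW", "HIGH"))
  df$sb <- factor(as.character(df$sb), levels = c("LOW", "HIGH"))
  cells <- table(df$sa, df$sb)
  prep <- cox_covariate_terms(df, covariates)
  df <- prep$df
  rhs <- paste(c("sa", "sb", prep$terms), collapse = " + ")
  fit <- tryCatch(
    survival::coxph(stats::as.formula(paste("survival::Surv(time, event) ~", rhs)),
                    data = df, ties = "efron"),
    error = function(e) NULL)
  combos <- data.frame(group_a = c("HIGH", "LOW", "HIGH"),
                       group_b = c("LOW", "HIGH", "HIGH"))
  combos$n <- mapply(function(a, b) cells[a, b], combos$group_a, combos$group_b)
  combos$hr <- NA_real_; combos$ci_low <- NA_real_; combos$ci_high <- NA_real_
  combos$inestimable <- combos$n == 0
  if (!is.null(fit)) {
    cf <- stats::coef(fit); V <- stats::vcov(fit)
    contrast <- function(wa, wb) {
      est <- wa * cf["saHIGH"] + wb * cf["sbHIGH"]
      se <- sqrt(wa^2 * V["saHIGH", "saHIGH"] + wb^2 * V["sbHIGH", "sbHIGH"] +
                   2 * wa * wb * V["saHIGH", "sbHIGH"])
      c(exp(est), exp(est - 1.96 * se), exp(est + 1.96 * se))
    }
    w <- list(c(1, 0), c(0, 1), c(1, 1))
    for (i in 1:3) {
      if (combos$inestimable[i]) next
      z <- contrast(w[[i]][1], w[[i]][2])
      combos$hr[i] <- z[1]; combos$ci_low[i] <- z[2]; combos$ci_high[i] <- z[3]
    }
  } else combos$inestimable <- TRUE
  combos
}

#' Cox model with score-by-subtype interaction
#'
#' Fits stratum, subtype and their interaction with reference
#' (LOW, `reference_subtype`) and reports one interaction hazard ratio per
#' non-reference subtype (the multiplicative change of the HIGH-vs-LOW
#' effect in that subtype relative to the reference subtype).
#'
#' @param clinical a `clinical_table` with a `subtype` column.
#' @param strata stratum labels from [tertile_groups()].
#' @param reference_subtype subtype coded as reference.
#' @return data frame with `subtype`, `hr`, `se`, `ci_low`, `ci_high`,
#'   `p`, `inestimable`; the reference subtype has no row.
#' @export
interaction_cox <- function(clinical, strata, reference_subtype) {
  df <- strata_frame(clinical, strata)
  if (!"subtype" %in% colnames(df)) stop("clinical table needs a subtype column")
  df <- df[!is.na(df$subtype), , drop = FALSE]
  subtypes <- unique(as.character(df$subtype))
  if (!reference_subtype %in% subtypes)
    stop("reference subtype '", reference_subtype, "' absent")
  if (length(subtypes) < 2L) stop("need >= 2 subtypes")
  df$subtype <- stats::relevel(factor(df$subtype), ref = reference_subtype)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ stratum * subtype,
                    data = df, ties = "efron"),
    error = function(e) NULL)
  others <- setdiff(levels(df$subtype), reference_subtype)
  out <- data.frame(subtype = others, hr = NA_real_, se = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                    inestimable = FALSE)
  for (i in seq_along(others)) {
    term <- paste0("stratumHIGH:subtype", others[i])
    no_high <- sum(df$stratum == "HIGH" & df$subtype == others[i]) == 0
    if (is.null(fit) || no_high || !term %in% names(stats::coef(fit)) ||
        is.na(stats::coef(fit)[term])) {
      out$inestimable[i] <- TRUE
      next
    }
    sm <- summary(fit)
    out$hr[i] <- unname(sm$conf.int[term, "exp(coef)"])
    out$se[i] <- unname(sm$coefficients[term, "se(coef)"])
    out$ci_low[i] <- unname(sm$conf.int[term, "lower .95"])
    out$ci_high[i] <- unname(sm$conf.int[term, "upper .95"])
    out$p[i] <- unname(sm$coefficients[term, "Pr(>|z|)"])
  }
  out
}

mutation_indicator <- function(mutations, gene, samples) {
  mut <- unique(mutations$sample_id[mutations$gene == gene])
  as.integer(samples %in% mut)
}

#' Driver-gene mutation association with iScores
#'
#' Per (gene, cell type), the linear model
#' `iScore_k ~ b0 + b_d * D + sum(b_n * C_n)` where `D` is the gene's 0/1
#' mutation status and `C_n` are cancer-type indicators (pan-cancer scope)
#' or subtype indicators (per-cancer scope). Genes are tested only where
#' mutated in more than `min_mutated` tumors in scope. FDR correction is
#' cancer-wise across all tested (gene, cell type) pairs; the reporting
#' convention flags `|coef| > 0.1` and `q < 0.1`.
#'
#' @param iscores samples x cell-types matrix.
#' @param mutations a `mutation_table`.
#' @param cancer_of named cancer-type label per sample.
#' @param genes genes to test; defaults to all genes in `mutations`.
#' @param min_mutated strict mutation-count floor, default 5.
#' @param scope `"pan-cancer"` or `"per-cancer"`.
#' @param subtype_of optional named subtype per sample (per-cancer scope
#'   covariates).
#' @return data frame with `scope`, `gene`, `celltype`, `coef`, `se`, `p`,
#'   `q`, `n_mutated`, `significant`.
#' @export
driver_association <- function(iscores, mutations, cancer_of,
                               genes = unique(mutations$gene),
                               min_mutated = 5L,
                               scope = c("pan-cancer", "per-cancer"),
                               subtype_of = NULL) {
  scope <- match.arg(scope)
  v <- unclass(as.matrix(iscores))
  samples <- rownames(v)
  run_scope <- function(scope_name, s, covar) {
    rows <- list()
    for (gene in genes) {
      D <- mutation_indicator(mutations, gene, s)
      nm <- sum(D)
      if (nm <= min_mutated) {
        message("gene ", gene, " mutated in ", nm, " tumor(s) in ",
                scope_name, ": excluded")
        next
      }
      for (ct in colnames(v)) {
        dat <- data.frame(y = v[s, ct], D = D)
        if (!is.null(covar) && length(unique(covar)) > 1L) dat$C <- factor(covar)
        fit <- stats::lm(y ~ ., data = dat)
        cf <- summary(fit)$coefficients
        if (!"D" %in% rownames(cf)) next
        rows[[length(rows) + 1L]] <- data.frame(
          scope = scope_name, gene = gene, celltype = ct,
          coef = cf["D", "Estimate"], se = cf["D", "Std. Error"],
          p = cf["D", "Pr(>|t|)"], n_mutated = nm)
      }
    }
    if (length(rows) == 0L) return(NULL)
    out <- do.call(rbind, rows)
    out$q <- bh_fdr(out$p)
    out
  }
  out <- if (scope == "pan-cancer") {
    run_scope("pan-cancer", samples, cancer_of[samples])
  } else {
    do.call(rbind, lapply(unique(cancer_of[samples]), function(cn) {
      s <- samples[cancer_of[samples] == cn]
      run_scope(cn, s, if (is.null(subtype_of)) NULL else subtype_of[s])
    }))
  }
  if (is.null(out))
    return(data.frame(scope = character(), gene = character(),
                      celltype = character(), coef = numeric(), se = numeric(),
                      p = numeric(), n_mutated = integer(), q = numeric(),
                      significant = logical()))
  out$significant <- abs(out$coef) > 0.1 & out$q < 0.1
  rownames(out) <- NULL
  out
}

#' MSI-H and POLE status association with iScores
#'
#' Per cell type, the joint linear model
#' `iScore_k ~ b0 + b_m * M + b_p * P + sum(b_n * C_n)` with the MSI-H and
#' POLE 0/1 flags and cancer-type indicators. Collinear or constant flags
#' are flagged inestimable rather than silently fit. Significance
#' convention q (FDR) < 0.1.
#'
#' @param iscores samples x cell-types matrix.
#' @param flags data frame with `sample_id`, `msi_h`, `pole`.
#' @param cancer_of named cancer-type label per sample (optional).
#' @return data frame with `celltype`, `term` (`msi_h`/`pole`), `coef`,
#'   `se`, `p`, `q`, `inestimable`.
#' @export
msi_pole_association <- function(iscores, flags, cancer_of = NULL) {
  v <- unclass(as.matrix(iscores))
  samples <- intersect(rownames(v), flags$sample_id)
  fl <- flags[match(samples, flags$sample_id), , drop = FALSE]
  M <- as.numeric(fl$msi_h); P <- as.numeric(fl$pole)
  collinear <- stats::sd(M) > 0 && stats::sd(P) > 0 &&
    abs(stats::cor(M, P)) > 1 - 1e-12
  rows <- list()
  for (ct in colnames(v)) {
    dat <- data.frame(y = v[samples, ct], M = M, P = P)
    if (!is.null(cancer_of) && length(unique(cancer_of[samples])) > 1L)
      dat$C <- factor(cancer_of[samples])
    fit <- stats::lm(y ~ ., data = dat)
    cf <- summary(fit)$coefficients
    for (term in c("M", "P")) {
      bad <- collinear || !term %in% rownames(cf) ||
        is.na(stats::coef(fit)[term]) ||
        stats::sd(dat[[term]]) == 0
      rows[[length(rows) + 1L]] <- data.frame(
        celltype = ct, term = if (term == "M") "msi_h" else "pole",
        coef = if (bad) NA_real_ else cf[term, "Estimate"],
        se = if (bad) NA_real_ else cf[term, "Std. Error"],
        p = if (bad) NA_real_ else cf[term, "Pr(>|t|)"],
        inestimable = bad)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  rownames(out) <- NULL
  out
}

#' Welch test of a specific variant against gene wild-type
#'
#' Compares the iScores of carriers of one specific variant (e.g.
#' `p.S249`) against samples with no mutation at all in the gene
#' (carriers of other variants of the same gene are excluded).
#'
#' @param iscores named numeric vector (one cell type's scores).
#' @param mutations a `mutation_table` with a `variant` column.
#' @param gene,variant the variant of interest.
#' @param min_carriers strict carrier floor, default 5 (`> 5` required).
#' @return list with `t`, `p`, `n_variant`, `n_wildtype`.
#' @export
variant_welch <- function(iscores, mutations, gene, variant,
                          min_carriers = 5L) {
  gm <- mutations[mutations$gene == gene, , drop = FALSE]
  carriers <- unique(gm$sample_id[gm$variant == variant])
  any_mut <- unique(gm$sample_id)
  samples <- names(iscores)
  grp_v <- iscores[samples %in% carriers]
  grp_wt <- iscores[!(samples %in% any_mut)]
  if (length(grp_v) <= min_carriers)
    stop("variant carried by ", length(grp_v), " sample(s); need > ", min_carriers)
  if (length(grp_v) < 2L || length(grp_wt) < 2L)
    stop("both groups need >= 2 samples")
  ht <- stats::t.test(grp_v, grp_wt, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       n_variant = length(grp_v), n_wildtype = length(grp_wt))
}

#' Compare iScores between high- and low-mutation-burden groups
#'
#' Groups are the top and bottom quartiles of the total mutation count
#' (synonymous plus non-synonymous); each cell type is tested by Welch's
#' t-test (default) or Mann-Whitney, with Benjamini-Hochberg FDR across
#' cell types (significance convention FDR < 0.05).
#'
#' @param iscores samples x cell-types matrix.
#' @param counts named total mutation count per sample.
#' @param test `"welch"` or `"mannwhitney"`.
#' @param fdr_threshold significance flag threshold, default 0.05.
#' @return data frame with `celltype`, `statistic`, `p`, `q`,
#'   `mean_high`, `mean_low`, `significant`.
#' @export
tmb_group_compare <- function(iscores, counts, test = c("welch", "mannwhitney"),
                              fdr_threshold = 0.05) {
  test <- match.arg(test)
  v <- unclass(as.matrix(iscores))
  samples <- intersect(rownames(v), names(counts))
  if (length(samples) < 4L) stop("need >= 4 samples with mutation counts")
  cnt <- counts[samples]
  q <- stats::quantile(cnt, c(0.25, 0.75), type = 7, names = FALSE)
  low <- samples[cnt <= q[1]]
  high <- samples[cnt > q[2]]
  if (length(low) < 2L || length(high) < 2L)
    stop("quartile group with < 2 samples")
  rows <- lapply(colnames(v), function(ct) {
    a <- v[high, ct]; b <- v[low, ct]
    ht <- if (test == "welch") stats::t.test(a, b, var.equal = FALSE)
          else stats::wilcox.test(a, b, exact = FALSE)
    data.frame(celltype = ct, statistic = unname(ht$statistic), p = ht$p.value,
               mean_high = mean(a), mean_low = mean(b))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr_threshold
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery control: with sorted p-values,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and mapped back to
#' the input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  adj <- rev(cummin(rev(pvalues[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(adj, 1)
  q
}
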