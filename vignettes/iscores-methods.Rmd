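---
title: "Methods: integrated TME deconvolution scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated TME deconvolution scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `iscores`, the
assumptions behind them, the tunable parameters and their defaults, the
numerical choices made where the design was genuinely open, and what the
synthetic benchmark does and does not demonstrate.

## Deconvolution backends

### Sparse group lasso

Bulk deconvolution treats a sample's expression over the signature genes
as a non-negative mixture of pure cell-type profiles. The backend fits,
independently per sample,

$$\min_\beta \frac{1}{2n}\Big\|y - \sum_{l=1}^{m} X^{(l)}\beta^{(l)}\Big\|_2^2
 + (1-\alpha)\lambda\sum_{l=1}^m \sqrt{p_l}\,\|\beta^{(l)}\|_2
 + \alpha\lambda\|\beta\|_1 ,$$

where the signature columns are partitioned into $m$ groups of related
cell types (sizes $p_l$) and $n$ is the number of signature genes. Related
subsets (e.g. the macrophage polarization states) are strongly collinear;
the group penalty lets the solver switch an entire family off, while the
lasso penalty selects within an active family. The mixing weight defaults
to $\alpha = 0.5$, an even compromise between the two penalties.

Solver: block-coordinate descent over groups. Each sweep first evaluates
the group soft-thresholding condition
$\|S(X_l^\top r_l/n,\ \alpha\lambda)\|_2 \le (1-\alpha)\lambda\sqrt{p_l}$
(with $S$ the coordinate-wise soft-threshold and $r_l$ the partial
residual), which zeroes the block exactly; otherwise the block is
minimized by proximal-gradient steps with step size $n/\|X_l\|_{op}^2$,
whose proximal operator composes soft-thresholding with group-norm
shrinkage. Both operations decrease the objective, so it is
non-increasing across sweeps (asserted in the tests). Convergence is
declared when the largest absolute coefficient change in a sweep falls
below `tol` (default `1e-7`; inner block iterations use `tol/10`, capped
at 1000 steps); `max_iter` defaults to 10,000 sweeps, and non-convergence
returns the best iterate with a warning.

Conventions fixed where the design was open:

* **No intercept, no sign constraint.** Coefficients are returned raw and
  may be negative; a `nonneg` option clamps at zero. Estimates are meant
  for cross-sample standardization, where an affine within-cell-type
  transformation is immaterial.
* **Linear (FPKM-like) scale.** No log transform is applied before
  regression; the signature lives on the same linear scale.
* **Internal standardization.** Signature columns are scaled to unit
  root-mean-square for penalty calibration ($\lambda_{\max}$) and
  cross-validation; coefficients are rescaled to the original column
  scale on return. Columns are not centered, which would break the
  non-negative mixture interpretation.

### Penalty selection

The observational units of the per-sample regression are genes, so
cross-validation partitions the signature genes into `folds = 5` folds. A
log-spaced grid of 30 penalties spans three decades down from
$\lambda_{\max}$ (the smallest penalty with an all-zero fit; computed
exactly, by 1D root finding per group for $0 < \alpha < 1$). The
held-out error curve is typically flat over a wide range of small
penalties, which makes the literal arg-min ill-conditioned with respect
to the random fold assignment: re-drawing folds moves the arg-min several
grid steps with no meaningful change in error. The selected penalty is
therefore the *largest* grid value whose mean held-out error is within 1%
of the minimum (`cv_rtol = 0.01`) — a mild variant of the one-standard-
error rule that prefers the most regularized model among statistically
indistinguishable ones and makes selection reproducible across fold
seeds.

For cohorts of more than 25 samples, `deconvolve_sgl()` cross-validates
the penalty on 10 evenly spaced samples and reuses the median, trading a
per-sample tuned penalty for an order-of-magnitude runtime reduction;
per-sample selection is retained for small cohorts and available via the
`lambda` argument.

### Rank-based single-sample gene-set scoring

Per sample, genes are ranked by expression with average ranks for ties
(deterministic). Walking the genes in decreasing rank order, the score of
a set $S$ is the summed difference between the weighted in-set ECDF
(weight $\mathrm{rank}^\tau$, $\tau = 0.25$) and the unweighted
out-of-set ECDF. The score depends on ranks only, hence is invariant to
any strictly increasing per-sample transform — the property that makes it
robust to normalization differences between cohorts. Cross-sample
normalization (dividing all scores by the global max − min) is on by
default and toggleable; it rescales but never reorders. Sets with fewer
than 3 members present in the expression matrix are skipped with a
warning.

### Non-negative least squares

`nnls_deconvolve()` wraps Lawson–Hanson NNLS (`pracma::lsqnonneg`)
per sample as the simple reference-matrix baseline; tests check its
objective against exhaustive sign-pattern enumeration on small problems.

## Integration into iScores

Per tool, each cell-type column is standardized across all samples,
$z = (x - \mu)/\sigma$, using the *sample* standard deviation
(denominator $n-1$); the convention is fixed and documented because the
definition leaves it open. Zero-variance columns carry no cross-sample
signal and are dropped with a warning; a single-sample table is an error.

Cell-type vocabularies are harmonized by a shipped, versioned,
user-extensible mapping table (`inst/extdata/celltype_mapping.tsv`):
(tool, tool name) → canonical name, plus a lineage flag (myeloid,
lymphoid, stromal, other) and a class (cell type vs process). Two columns
of one tool mapping to the same canonical name are first averaged within
the tool; unmapped columns are excluded from integration but exported on
a side channel rather than dropped silently.

The iScore of a (sample, cell type) is the arithmetic mean of the
z-scores from every tool reporting that cell type — a cell type measured
by one tool keeps that tool's z-score. The leukocyte and stromal
aggregates average the *tool-level* standardized scores (not the
already-averaged iScores), following the aggregate definitions' wording;
consequently a cell type measured by three tools carries three times the
weight of one measured once, a choice we fix and document because the
alternative (equal weight per cell type) is equally defensible.
Process-class signatures contribute to neither aggregate. iScores support
cross-sample comparison of a given cell type; they are not within-sample
proportions, and the package deliberately offers no simplex
renormalization.

## The synthetic benchmark

`simulate_cells()` emulates a labeled scRNA-seq count matrix: log-normal
baseline means per gene (meanlog $\log 2$, sdlog 1 — a right-skewed,
FPKM-like mean distribution), disjoint marker blocks up-regulated
`marker_fold`-fold in their own type, and negative-binomial counts
(variance $\mu + \phi\mu^2$, dispersion $\phi = 0.5$ — overdispersion in
the range typical of UMI data; $\phi = 0$ gives Poisson). The benchmark
conditions are 5 types, 2000 genes, 500 cells per type, fold 8, with all
labels known; an `unlabeled_frac` option hides labels to exercise the
classifier path.

Pseudobulks are gene-wise **sums** of `round(0.10 × N)` cells drawn
without replacement (1000 mixtures by default) — sums rather than means
preserve library-size structure. True fractions are the sampled type
proportions, so every row sums to 1 by construction and the mixture
matrix conserves counts exactly. Cells labeled `UNLABELED` or `AMBIGUOUS`
are excluded before sampling, mirroring the rule of removing cells whose
marker expression does not support their label; the qualitative
"consistent with the expected signature" criterion is exposed
quantitatively as the `min_margin` gap in `label_by_markers()`.

The classifier ensemble (`classify_unlabeled()`) balances training
classes by down-sampling to the median class size, trains `k_models = 5`
linear support-vector classifiers on the 5 cross-validation complements,
and flags a cell `AMBIGUOUS` when the Shannon entropy (natural log) of
its 5 votes exceeds `log(2)` — the entropy of a 50/50 split, a natural
scale point; the threshold is a parameter because no canonical value
exists. Any deterministic maximum-margin or logistic linear separator
would satisfy the contract; the SVM was chosen as the conventional one.

Batch correction toward the signature's scale is location-only:
per shared gene, `value − batch mean + reference mean`, with no variance
adjustment — hence exactly idempotent, and a no-op for batches already
aligned in means. Full empirical-Bayes batch correction (variance
pooling, parametric priors) is out of scope by design.

**What passing the benchmark shows — and does not.** The generator
produces well-separated types with disjoint markers, independent genes
given the type, and no ambient contamination, doublets, dropout
structure beyond NB noise, or batch effects between cells. High recovery
correlations under these conditions validate the *pipeline mechanics*
(mixing, scoring, standardization, averaging) and the solvers, not
performance on real tumors, where marker overlap and correlated
expression make deconvolution strictly harder.

## TME map and clustering

The published interactive projection service used for the original TME
map is not reproducible locally; the package substitutes a documented
contract: a k-nearest-neighbor graph (`k_neighbors = 15`) on iScore
vectors under correlation distance, laid out by the Fruchterman–Reingold
algorithm with a fixed seed. The contract is (a) determinism given the
seed, and (b) for well-separated groups in iScore space, smaller mean
within-group than between-group 2D distance. Identical input profiles
are collapsed before layout and share coordinates exactly. Missing
iScores are mean-imputed per cell type with a warning. The exact
geometry of any particular published map is not claimed.

Clustering of the 2D coordinates is an in-package implementation of the
HDBSCAN family (no R implementation was available among the package's
allowed dependencies): core distances at `min_samples` =
`min_cluster_size` neighbors, mutual-reachability minimum spanning tree,
single-linkage hierarchy, condensation at `min_cluster_size = 20`, and
excess-of-mass cluster selection by stability; unabsorbed points are
noise. The hierarchy root is not selectable by default
(`allow_single_cluster = FALSE`), so datasets with no density structure
return all-noise rather than one giant cluster. The procedure involves
no randomness, so determinism is structural.

Per-cluster tests compare every cluster of at least 5 samples against the
group's largest cluster: Welch (unequal-variance) t-tests per iScore —
"t-test" left unqualified is taken as Welch, the safer default — with the
leukocyte aggregate always reported plus the five smallest-p iScores; and
Cox proportional-hazards models of cluster membership adjusted for
subtype, with the separation p-value from the two-group log-rank test.
The progression endpoint is the default; overall survival substitutes for
cancers flagged as lacking it (`no_pfs = "LAML"`).

## Survival and somatic-alteration models

Tertile stratification cuts at the type-7 empirical 1/3 and 2/3 quantiles
of the score's **global** distribution; boundary ties go to the lower
stratum, making labels deterministic. LOW is the reference everywhere.
Whether per-cancer analyses should instead use per-cancer tertiles is
ambiguous; the package defaults to global tertiles (matching the "global
distribution" reading) and exposes the alternative by simply passing
per-cancer scores.

Cox models use Efron tie handling (the standard default of the R
survival stack). Pan-cancer models adjust for cancer type, localization,
age and gender, with stage added where available; missing covariate rows
are listwise-deleted per fit with the count reported. Per-cancer p-values
are corrected across cancers by Benjamini–Hochberg (q < 0.1 convention).
Strata without events are flagged inestimable rather than fit. The
additive two-score model reports each non-reference joint group against
the double-LOW reference, combining coefficients with delta-method
standard errors; the interaction model reports one interaction hazard
ratio per non-reference subtype.

Mutation models are ordinary linear models per cell type:
`iScore ~ b0 + b_d D + Σ b_n C_n` (driver status with cancer-type
indicators pan-cancer, subtype indicators per cancer) and
`iScore ~ b0 + b_m M + b_p P + Σ b_n C_n` for the MSI-H/POLE flags.
Genes enter only when mutated in **more than** `min_mutated = 5` tumors
in scope (a strict inequality); the reporting convention flags
`|coef| > 0.1` and `q < 0.1`. Collinear or constant flags are flagged
inestimable, never silently dropped. Variant-level tests compare carriers
of one specific variant against gene wild-type samples — carriers of
*other* variants of the same gene are excluded from the comparison group
— by Welch's t-test, requiring more than 5 carriers. The
mutation-burden comparison contrasts the top and bottom count quartiles
per cell type (Welch by default, Mann–Whitney available), FDR < 0.05
marking. The FDR family for per-cancer survival runs is across cancers
(per cell type); for the mutation screens it is cancer-wise across the
tested (gene, cell type) pairs — the screen-level family for the
pan-cancer driver model is not fully determined by the source material,
and the package fixes the genes × cell-types family.

`bh_fdr()` implements the step-up rule
$q_{(i)} = \min_{j \ge i} p_{(j)} m / j$ capped at 1; tests verify exact
agreement with the reference implementation on random inputs.

## Problem sizes and determinism

All stochastic tests and the acceptance script run at fixed seeds with
documented replicate counts: 20 random problems for the solver oracles,
1000 pseudobulks at 10% sampling for the recovery benchmark, 100
replicates for null-coverage checks, 100 null genes for FDR control.
These sizes give stable pass/fail behavior at conventional tolerances
while keeping a full run in the low minutes on one core.

## Known limitations

* Estimates are relative (z-score scale); no absolute fractions, no
  within-sample composition.
* The harmonization map ships with the cell types exercised by the
  package and common external-tool vocabularies; real multi-tool cohorts
  will need user extensions of the TSV.
* The synthetic generator omits several properties of real scRNA-seq
  (correlated programs, dropout, doublets, ambient RNA), so benchmark
  results bound the pipeline's correctness, not its field performance.
* The 2D embedding is a documented substitute with a separation
  contract, not a reproduction of any published projection's geometry.
* External tools (SVR-based, spillover-corrected, or constrained-fraction
  deconvolution methods) are consumed only through the estimate-table
  adapter, never re-implemented.
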