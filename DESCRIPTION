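Package: iscores
Title: Integrated Cell-Type Scores for Tumor Microenvironment Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolves bulk tumor expression profiles into tumor
    microenvironment cell-type abundances with a sparse-group-lasso
    regression backend, a rank-based single-sample gene-set scorer and a
    non-negative least-squares baseline, then integrates per-tool estimates
    into per-cell-type z-score averages (iScores) with leukocyte and stromal
    aggregates. Includes a labeled single-cell simulator and pseudobulk
    benchmarking with known mixing fractions, location-only batch
    correction, a density-clustered two-dimensional TME map with per-cluster
    differential and survival comparisons, and survival and
    somatic-alteration association models (tertile Cox proportional
    hazards, driver-gene and hypermutation linear models, tumor mutation
    burden group tests) with Benjamini-Hochberg false discovery control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pracma,
    e1071,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
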