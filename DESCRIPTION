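Package: sfcoupling
Title: Structure-Function Coupling Analysis for MEG and Diffusion MRI Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the relationship between structural brain
    connectivity (mean fractional anisotropy per white-matter tract) and
    resting-state functional connectivity estimated from source-level
    magnetoencephalography time series. Functional connectivity is the
    corrected amplitude envelope correlation (AECc): narrowband FFT
    band-pass filtering, pairwise time-domain orthogonalization to suppress
    zero-lag signal leakage, Hilbert amplitude envelopes, and Pearson
    correlation of envelopes. Structural edges are stratified into short-
    and long-range classes by quartiles of the pooled healthy-control
    tract-length distribution. The package computes within-subject
    structure-function coupling and between-subject correlations per edge
    class, covariate-adjusted general linear model group comparisons with
    Bonferroni control, ROC biomarker evaluation of coupling for cognitive
    impairment, and ships a synthetic cohort generator with plantable
    group effects so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
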