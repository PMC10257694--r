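Package: diascore
Title: Generalizable Precursor Scoring and FDR Control for DIA Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Search-space-agnostic statistical validation of data-independent
    acquisition (DIA) mass-spectrometry peak groups. Provides noisy-label
    denoising of target annotations by per-sample k-fold ensemble voting,
    generalizable precursor classifiers (a stochastic-gradient linear
    hinge-loss model and gradient-boosted trees) trained with class-imbalance
    weights on MS2-level subscores, prediction-gated false discovery rate
    control with spline-density and decoy-counting q-values, global
    peptide/protein score rollup, annotated quantitative-matrix export, and
    evaluation utilities (entrapment FDR curves and spike-in ratio
    validation), exercised end-to-end on a bundled synthetic peak-group
    simulator with ground-truth labels.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
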