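Package: cpgc
Title: Correlation-Purged Granger Causality for Resting-State Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Directed (effective) connectivity analysis for resting-state
    fMRI region-of-interest time series using correlation-purged Granger
    causality: a structural vector autoregression with an instantaneous
    coefficient matrix (zero diagonal) absorbs zero-lag correlation so that
    lagged coefficients are purged of correlation leakage. Includes ROI
    sphere-mask construction from a coordinate table, band-pass filtering,
    nuisance regression, framewise-displacement motion QC, phase-randomized
    surrogate null distributions with Fisher-combined within-group inference,
    covariate-adjusted between-group contrasts with within-group masks,
    connectivity-behavior correlations, and a synthetic two-group cohort
    generator with planted causal structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    RNifti,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
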