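Package: smcflex
Title: Worm-Like-Chain Flexibility and Conformational Dynamics of SMC Dimers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of single-molecule atomic force microscopy
    (AFM) movies of structural-maintenance-of-chromosomes (SMC) dimers such as
    condensin Smc2-Smc4. Provides a two-dimensional worm-like-chain (WLC)
    Monte-Carlo simulator, persistence-length and contour-length estimation by
    least-squares comparison of end-to-end distance histograms with Monte-Carlo
    parametric confidence intervals, a moment-based persistence-length
    estimator, per-frame conformational geometry (head-head and head-hinge
    distances, hinge angles) with V/O/B/P classification and state-transition
    statistics, and a synthetic movie generator for validating every stage of
    the pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
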