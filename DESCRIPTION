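Package: shaman
Title: Split-Half Analysis of Motion-Associated Networks for Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns trait-specific motion impact scores (omnibus,
    overestimation, and underestimation) to trait-functional-connectivity
    effects in parcellated resting-state fMRI via split-half analysis of
    motion-associated networks (SHAMAN). Each participant's timeseries is
    split into low- and high-motion halves by framewise displacement,
    between-participant motion is residualized out of each half's Fisher-z
    edge vector, and the trait is regressed against the half differences.
    Significance is obtained by a motion-blocks permutation scheme that
    preserves temporal autocorrelation, combined across edges with
    non-parametric combining (Stouffer's Z). Includes a generative
    simulator of motion-contaminated parcellated BOLD cohorts with
    design-controlled trait and motion mixing, frame censoring and
    data-quantity quality control, node-level scores with iterative region
    exclusion, and companion trait-FC/motion-FC edgewise regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
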