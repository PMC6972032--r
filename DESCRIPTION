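Package: hipmsm
Title: Multi-State Markov Models for Interval-Censored Hip Osteoarthritis Panel Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Continuous-time Markov multi-state models for interval-censored
    panel observations of hip osteoarthritis states (no disease, asymptomatic
    radiographic OA, symptoms only, symptomatic OA, death), with time-dependent
    comorbidity covariates carried forward between visits, a piecewise-constant
    intensity changepoint at age 65, and exact death times from registry
    linkage. Provides maximum-likelihood fitting with Wald confidence
    intervals, hazard-ratio tables for individual and combined comorbidity
    exposures, observed-versus-expected prevalence assessment, a calibrated
    synthetic cohort generator emulating a community-based OA cohort, and an
    analysis pipeline covering overall, pairwise-combination, triple-combination
    and sex/race-stratified models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
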