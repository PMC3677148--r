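Package: opmom
Title: Operational Momentum in Non-Symbolic Arithmetic: Stimulus Design,
    Cohort Simulation, and Heteroscedastic Bayesian Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the operational momentum (OM) effect in
    non-symbolic approximate arithmetic. Reconstructs the geometric
    deviant-series stimulus design and trial schedules of a choice-based
    addition/subtraction paradigm, simulates child and adult cohorts whose
    choices obey Weber's law on a log-compressed magnitude scale, computes
    the descriptive statistics of the paradigm (log-scale response bias,
    coefficient-of-variation profiles, choice-rank distributions, Posner
    cueing orienting and reorienting effects), and fits a heteroscedastic
    bivariate-normal repeated-measures model with group-specific covariance
    matrices by a purpose-built Gibbs sampler with inverse-Wishart priors,
    summarised by highest-density intervals and posterior sign
    probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
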