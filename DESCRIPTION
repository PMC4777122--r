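Package: fwreg
Title: Finlay-Wilkinson Regression with Genomic and Environmental Covariances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying genotype-by-environment interaction with the
    Finlay-Wilkinson reaction-norm regression. Implements the classical
    two-step estimator (constrained main-effects least squares followed by
    within-line regression on estimated environment effects) and a
    single-step Bayesian model in which variety intercepts, variety slopes
    and environment effects are random, with optional marker- or
    pedigree-derived covariance between varieties and a covariance
    structure between environments, fitted by a blocked Gibbs sampler with
    scaled-inverse-chi-square priors on the variance components. Includes
    a synthetic-data generator with kinship simulation, cross-validation
    utilities for prediction accuracy, MCMC summaries and diagnostics, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
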