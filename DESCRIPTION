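Package: lesionkinetics
Title: Piecewise-Linear Mixed-Effects Analysis of RECIST Target-Lesion Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the time course of individual RECIST target
    lesions under treatment. Implements a mechanistically motivated
    piecewise-linear growth model (linear decay to a switch point, linear
    re-growth after it) within a two-level mixed-effects framework
    (lesions nested in patients), with maximum-likelihood estimation via a
    Laplace-approximated marginal likelihood (adaptive Gauss-Hermite
    quadrature available as an oracle backend), switch-point selection over
    visit-midpoint candidates by log-likelihood, between-/within-patient
    variance decomposition of shrinkage and re-growth rates, and a seeded
    synthetic RECIST-style cohort generator for validation.
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
    lme4,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
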