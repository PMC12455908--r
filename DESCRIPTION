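Package: censgp
Title: Exact Gaussian Process Regression for Value-Censored Functional Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact empirical Bayes Gaussian process regression when some
    observations are value-censored (left-, right-, or interval-censored),
    as happens below assay detection limits or above sensor saturation.
    Provides closed-form observed-data likelihoods, exact conditional
    posterior samplers built from box-truncated multivariate normal draws,
    a multi-level model for several curves around a common mean with a
    sum-to-zero deviation prior, an empirical Bayes fitting procedure, and
    a simulation and coverage study harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    pracma,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    jsonlite
Config/testthat/edition: 3
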