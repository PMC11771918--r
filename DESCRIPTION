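Package: gfvicm
Title: Generalized Functional Varying-Index Coefficient Models for
    Binary Longitudinal Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits generalized functional varying-index coefficient models
    (gFVICM) for binary longitudinal traits, in which the effect of a
    genetic variant on disease risk is modified nonlinearly by a linear
    index of environmental exposures. Index coefficient functions are
    approximated by penalized truncated power splines and estimated by
    quadratic inference functions (QIF) with a profile algorithm; tuning
    is by generalized cross-validation and BIC; QIF difference tests
    include a test for linearity of the gene-environment interaction
    function. Also provides a correlated-binary longitudinal simulator
    (Gaussian copula with per-pair latent correlation solves) and a Monte
    Carlo harness for coverage and size/power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
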