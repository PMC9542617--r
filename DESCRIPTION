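Package: svctrend
Title: Spatially Varying Coefficient Trend Models for Count-Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage Bayesian analysis of relative-abundance trends from
    effort-structured count surveys (e.g. butterfly count circles). Stage one
    fits a negative-binomial spatially-varying-coefficient model in which
    cell-level intercepts, effort exponents and log-linear year trends carry
    scaled intrinsic conditional autoregressive (iCAR) priors with penalized
    complexity hyperpriors, using a Hamiltonian Monte Carlo sampler. Stage two
    converts posterior draws into annual relative-abundance indices and fits a
    gamma covariate model (pesticide use, temperature, precipitation) with
    iCAR-structured spatial slopes repeatedly over posterior replicates to
    propagate uncertainty. Includes a synthetic-data generator emulating
    citizen-science count circles on a uniform 50-km grid, data-curation
    filters, county-to-cell covariate construction, and the iCAR structure
    matrix scaling and PC-prior utilities shared by both stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
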