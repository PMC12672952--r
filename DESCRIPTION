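Package: vascareless
Title: Beta Mixture Item Response Models for Careless Responding in
    Visual Analogue Scale Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a Bayesian Beta mixture item response model to bounded
    continuous questionnaire responses (visual analogue scales scored in
    the open unit interval) in order to detect and adjust for careless
    respondents.  Attentive responses follow a Beta item response model
    with a logistic expected-response curve and an item dispersion
    parameter; careless responses are absorbed by a single unstructured
    Beta component shared across persons and items.  Individual
    attentiveness probabilities receive a hierarchical Dirichlet prior.
    The package includes a simulation engine for contaminated response
    matrices, two classification rules with confusion-matrix metrics, a
    replication study harness, and a deliberately mis-specified normal
    mixture factor-analysis baseline for comparison.  Estimation is by
    adaptive Metropolis-within-Gibbs MCMC with Gelman-Rubin convergence
    diagnostics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
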