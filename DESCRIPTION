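Package: rangediv
Title: Comparative Analyses of Geographic Range Size and Speciation Rate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing how geographic range size, range shape and
    position, dispersal ability and body size relate to speciation rate
    across a clade. Implements tip-level diversification rate estimation
    (the inverse equal-splits DR statistic), phylogenetic generalized
    least squares with maximum-likelihood Pagel's lambda including
    island/continent interactions and split fits, phylogenetic path
    (structural equation) models fitted equation-by-equation, binary
    state-dependent speciation-extinction likelihoods (BiSSE, HiSSE and
    character-independent CID null models) with AIC model tables, the
    nonparametric FiSSE test, a joint spatial-phylogenetic mixed model
    with Matern spatial covariance, planar range-geometry metrics, and a
    seeded synthetic-data generator so every stage is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
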