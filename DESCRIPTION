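Package: glacialsplit
Title: Demographic Inference and Climate-Linked Range Dynamics for
    Glacial-Age Population Splits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dating population splits from genotype-likelihood
    data and linking them to episodes of rapid climate change. Implements
    maximum-likelihood minor-allele-frequency estimation from genotype
    likelihoods with polymorphism tests and site filters, construction of
    one- to three-dimensional site frequency spectra, expected joint
    spectra under split-with-migration demographic models via a
    moment-system engine, Poisson composite-likelihood fitting with
    multi-start optimization and real-unit conversion through a direct
    mutation rate, paleoclimate rate-of-change statistics with
    rapid-episode detection, and a TSS-gated species-distribution-model
    ensemble with multivariate environmental similarity surfaces. A
    synthetic-data module (structured-coalescent simulator, read-based
    genotype-likelihood model, climate and landscape generators) provides
    ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    glmnet,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
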