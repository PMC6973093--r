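Package: ratescape
Title: Variable-Rates Phylogenetic Regression and Evolutionary Trend Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects heterogeneity in the rate of trait evolution within a
    phylogenetic generalized least squares (GLS) regression. A reversible-jump
    Markov chain Monte Carlo sampler estimates branch-specific rate scalars over
    a Brownian-motion background rate in the residuals of a trait-on-covariate
    regression (e.g. testes mass on body mass across vertebrates). Includes
    stepping-stone estimation of marginal likelihoods for Bayes-factor
    comparison against a single-rate model, detection of heritable rate shifts
    (clades inheriting a new rate), mean-shift diagnosis, path-wise rates, and
    directional-trend regressions with social-mating-system interactions on the
    median rate-scaled tree. Ships a birth-death trait simulator with planted
    rate shifts and planted trends so the whole pipeline is testable against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
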