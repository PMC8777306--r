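Package: ontopool
Title: Ontology-Structured Bayesian Hierarchical Meta-Analysis of
    Comorbidity-Treatment Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for evaluating partial pooling of
    comorbidity-treatment interaction estimates across a network of
    clinical trials nested in drugs nested in WHO-ATC drug classes.
    Simulates trial-level interaction estimates under a three-level
    hierarchical data-generating process, fits an ontology-structured
    Bayesian hierarchical model (conjugate Gibbs sampler with slice
    updates for scale parameters) and comparator single-drug
    random-effects meta-analysis models, and computes simulation-study
    performance measures (bias, MSE, RMSE, relative precision, coverage,
    detection proportions) with Monte Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    coda,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
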