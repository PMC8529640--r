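Package: recovmix
Title: Mixture Latent Markov Models for Recovery States in Psychotic Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of mixture latent Markov models (MLMM) for yearly
    panel data on clinical, societal and personal recovery in schizophrenia
    spectrum disorders. Twelve mixed-type indicators (eight remission items of
    the Positive and Negative Syndrome Scale, three functional-recovery items
    and a single-item happiness score) are modelled jointly through a small
    number of latent recovery states with annual transition probabilities,
    optionally stratified by latent classes with class-specific dynamics.
    Provides EM estimation with multiple random starts and item-level
    missingness, BIC-based model selection under minimum state/class size
    constraints, canonical state ordering, occupancy and transition summaries,
    dichotomous recovery classifiers used in the remission literature,
    three-step covariate association with classification-error correction, and
    a synthetic panel generator emulating a naturalistic yearly cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
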