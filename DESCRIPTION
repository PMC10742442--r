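Package: cohesr
Title: Incoherence and Cohesion Measures for Ensembles of Replicate Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the replicability of stochastic simulations and
    experiments. Given an ensemble of replicate outcome distributions it
    computes incoherence (the weighted spread of per-replicate entropies
    around the entropy of the pooled distribution) and cohesion (a measure
    of how tightly replicates cluster into a small number of scenarios,
    derived from the density-variance entropy of the set of pairwise
    Jensen-Shannon divergences). Includes a bin-free continuous entropy
    estimator based on the variance of a square-rooted exponential-kernel
    density profile, an organised-noise message generator, and a seeded
    port of the Daisyworld agent-based model with a luminosity-sweep
    harness for tipping-point detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
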