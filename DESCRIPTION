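Package: saxdiv
Title: Clade-Partitioned Birth-Death and State-Dependent Diversification Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting diversification-rate shifts and
    state-dependent diversification on time-calibrated phylogenies.
    Implements constant-rate pure-birth and birth-death likelihoods with
    incomplete-sampling corrections, clade-partitioned rate-regime models
    with parameter linking, Metropolis-Hastings sampling with
    thermodynamic-integration marginal likelihoods and Bayes factors,
    BiSSE/MuSSE and GeoSSE state-dependent speciation-extinction
    likelihoods with state-specific sampling fractions, constraint-based
    model enumeration with AIC/Akaike-weight model selection, a
    trait-simulation delta-AIC null to guard against false positives, and
    forward simulators for birth-death trees, rate-shift trees, Markov
    characters and joint tree-plus-state processes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phytools,
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
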