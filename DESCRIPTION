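Package: hypersse
Title: Trait-Combination-Dependent Diversification on Binary-Character Hypercubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of character transitions and state-dependent
    diversification for sets of binary characters coded as a single multistate
    character on a hypercube. Implements the multistate speciation-extinction
    (MuSSE-type) pruning likelihood with state-specific sampling fractions and a
    fixed root state, tied-rate model families defined over focal/non-focal
    bipartitions of the combination network, exhaustive bipartition model search
    with AIC ranking, Akaike weights and model-averaged rates, exact stochastic
    simulation of birth-death-with-transition processes (full trees and
    counts-only), stationary (equilibrium) frequencies of trait combinations
    from the linear mean-growth dynamics, and generators for study-shaped
    synthetic datasets including stratified taxon sampling with dynamic
    rounding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
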