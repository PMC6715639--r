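Package: mergm
Title: Multilevel Exponential Random Graph Models for Collaboration
    Networks over Causal Loop Diagrams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the joint structure of a directed collaboration network
    among community steering-committee members and the bipartite "action"
    ties linking members to variables of a causal loop diagram (CLD), with
    the CLD itself and member attributes held exogenous. Provides the
    multilevel network data model and edge-list I/O, a catalogue of
    within-level, bipartite and cross-level configuration statistics
    (alternating stars and closures, cross-level three-paths and
    four-cycles) with exact change statistics, Metropolis tie-toggle MCMC
    simulation, Robbins-Monro stochastic-approximation maximum-likelihood
    estimation with convergence diagnostics, simulation-based goodness of
    fit, and a synthetic community generator for end-to-end parameter
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
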