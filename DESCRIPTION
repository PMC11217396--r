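Package: bowtieevo
Title: Evolution of Bow-Tie Architecture in Layered Signaling Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evolutionary simulation and dynamical-systems analysis of
    bow-tie (hourglass) architecture in layered linear signaling networks.
    Provides a genetic algorithm with multiplicative (product-rule) link
    mutation evolving stacks of nonnegative link matrices toward a goal
    in-out matrix, node-deletion importance statistics and waist/bow-tie
    detection, synthetic goal-matrix generation with controlled rank and
    Frobenius norm (including variance-and-norm normalization, goal
    fluctuation schedules and goal expansion), a multiplicative
    gradient-descent ODE model with its reduced two-node analysis and
    closed-form divergence time, a tanh-activated nonlinear classification
    variant on synthetic digit images, and reproducible experiment drivers
    for the figure-level protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
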