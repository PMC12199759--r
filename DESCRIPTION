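Package: growthperc
Title: Growth-Induced Percolation on Complex Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and mean-field theory for growth-induced percolation,
    a cascade model in which an inactive node becomes active when at least one
    of its active (incoming) neighbours itself has at least m active (incoming)
    neighbours, i.e. activation spreads through second-neighbour influence.
    Provides Erdos-Renyi and configuration-model network generators with
    Poisson and power-law degree distributions, an event-driven cascade
    simulator for the growth (activation) and retention (deactivation)
    processes with giant-component measurement (GCC, GSCC, GOUT),
    self-consistent mean-field solvers for directed and undirected networks
    with arbitrary degree distributions, and tools that scan control
    parameters, classify phase transitions (continuous, hybrid, first-order),
    locate critical points, measure jump-height scaling, and construct
    growth-versus-retention hysteresis loops.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
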