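Package: sbmlfit
Title: SBML Model Simulation and Heuristic Parameter Estimation
Version: 0.1.0
Authors@R: person("sbmlfit", "developers", role = c("aut", "cre"),
    email = "sbmlfit@example.org")
Description: Interprets biochemical network models encoded in the Systems
    Biology Markup Language (SBML, Level 2/3 core subset) as ordinary
    differential equation systems, simulates them with adaptive stiff
    (Rosenbrock) and non-stiff (Dormand-Prince) integrators including
    discrete-event handling, and calibrates uncertain parameters against
    time-series data with nature-inspired optimizers (differential
    evolution, evolution strategies, particle swarm optimization, hill
    climbing, simulated annealing).  Practical identifiability is assessed
    by repeating estimations and summarizing the spread of the best
    fraction of fits.  Includes a synthetic compartmental
    Michaelis-Menten chain model generator for fully reproducible
    estimation studies and a command-line interface for script-based use.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
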