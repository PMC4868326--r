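Package: angiokin
Title: Microscopic Kinetics of Tumour-Induced Angiogenesis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and stochastic analysis of a microscopic
    birth-death model of tumour angiogenesis coupling tumour cells,
    VEGF proteins and vessel (endothelial) cells.  Provides the
    reaction scheme and its macroscopic ODE limit, steady-state
    enumeration and saddle-node bifurcation scans, exact Gillespie and
    chemical-Langevin simulation with absorbing-state bookkeeping,
    particle-swarm parameter estimation against tumour-volume growth
    curves, perturbation sensitivity analysis, and a synthetic growth
    data generator calibrated to Lewis lung carcinoma.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    lhs,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
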