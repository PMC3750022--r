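Package: phoswitch
Title: Bistable Switching Dynamics in the PhoQ/PhoP Two-Component System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic and stochastic models of a bifunctional
    two-component signaling circuit with positive transcriptional
    autoregulation, built around the phosphatase-deficient PhoQ (T281R)
    variant of the E. coli PhoQ/PhoP system. Provides steady-state and
    saddle-node bifurcation analysis (monostable OFF / bistable /
    monostable ON regime classification, 1-D sweeps and 2-D bistability
    maps), an exact Gillespie simulator with cell-division partitioning
    for priming, switching and bimodality statistics, in-silico
    emulation of culture protocols (exponential vs stationary-phase
    lineages, induction hysteresis of a decoupled circuit, serial
    dilution with stationary-phase selection), the quantification
    statistics used for single-cell reporter data (YFP/CFP
    classification, competitive ratio and index, binomial inoculum
    arithmetic), and a synthetic single-cell data generator.
License: MIT
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
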