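Package: dscircuit
Title: Compartmental Modelling and Analysis of Retinal Direction Selectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing direction-selective retinal
    ganglion cell (DSGC) responses. Provides a procedural planar dendritic
    arbor with tri-receptor synapses (AMPA, nicotinic, GABA-A), sigmoidal
    direction tuning of release probability and spatial offset, moving-bar
    activation scheduling, a multi-compartment Hodgkin-Huxley cable
    simulator with current- and voltage-clamp modes, electrophysiology
    statistics (Gaussian-kernel firing rates, vector-sum direction
    selectivity index, 20-80 percent rise-fit onset latencies,
    excitation/inhibition temporal offsets, phase-resolved tuning), a
    synthetic-recording generator with known ground truth, and experiment
    drivers for mechanism-dissection and velocity-sweep studies.
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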