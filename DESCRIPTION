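Package: aglif
Title: Adaptive Generalized Leaky Integrate-and-Fire Neuron Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and fitting toolkit for the adaptive generalized leaky
    integrate-and-fire (A-GLIF) point-neuron model of hippocampal CA1 pyramidal
    neurons and interneurons. Provides exact closed-form trajectories of the
    three-variable linear membrane system, equilibrium and stability analysis
    with the parameter constraints that guarantee subthreshold silence,
    Monod-type after-spike update rules for the adaptation current including a
    firing-block procedure, event-driven simulation under constant and
    piecewise-constant current injection, genetic-algorithm fitting of model
    parameters to spike-time rasters with Monod interpolation of the fitted
    adaptation sequences, statistical validation of spike trains, and a
    synthetic-data generator producing ground-truth cells and rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
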