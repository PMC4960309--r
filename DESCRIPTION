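Package: spikegrid
Title: MAP Spike Inference from Calcium Fluorescence on a Discretized
    State Grid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model-based spike-train estimation from single-neuron calcium
    fluorescence recordings. Implements a generative model of spiking-driven
    fluorescence with exponential calcium decay, probe nonlinearities (dye
    saturation, GECI supra-linearity, Hill binding with finite rise time) and
    a drifting multiplicative baseline; a maximum-a-posteriori spike-train
    estimator based on a Viterbi-style backward recursion over a discretized
    (calcium, baseline) state space with spline interpolation; forward-backward
    smoothing for per-bin spike probabilities and posterior sampling of spike
    trains; per-neuron autocalibration of the transient amplitude, decay time
    constant and noise level; simulation of spike trains and calibrated white,
    drift and pink noise; and spike-train evaluation metrics (error rate,
    temporal precision, rate correlation, band-limited noise level,
    photomultiplier gain calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Matrix,
    Rcpp,
    withr,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'methods.R'
    'synth.R'
    'metrics.R'
    'model.R'
    'infer.R'
    'autocal.R'
    'benchmark.R'
    'io.R'
    'spikegrid-package.R'
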