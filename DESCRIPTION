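Package: akgain
Title: A-Type Potassium Current as a Switch Between Divisive and
    Subtractive Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a conductance-based neuron model in
    which the A-type potassium current (I_A) controls whether synaptic
    inhibition rescales (divisive) or right-shifts (subtractive) the firing
    rate input/output relation.  Provides Poisson and periodic synaptic
    event generators with reset-and-decay conductance gating, fast
    point-neuron and soma-dendrite cable simulators, threshold-linear
    characterisation of inhibited versus uninhibited rate curves, and the
    reduction theory for the instantaneous-activation model: V-nullcline
    knee analysis, the critical conductance at which excitability is lost,
    minimum responsive input rates, and a dead-time-modified Poisson
    approximation of output firing rates with an inhibition-dependent
    firing threshold.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
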