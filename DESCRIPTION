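Package: swdnet
Title: Dynamical Mesoscale Network Model of Spike-and-Wave Discharges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of absence-seizure spike-and-wave
    discharges (SWDs) in a two-level delay-coupled FitzHugh-Nagumo network of
    the cortico-thalamo-cortical circuit. Provides structured random
    connectivity generation for focal and surrounding subnetworks, screening
    of candidate coupling matrices, seizure initiation, maintenance and
    termination protocols (including 130 Hz high-frequency stimulation),
    local-field-potential observables with SWD detection and duration
    statistics, and an adapted nonlinear Granger-causality (prediction
    improvement) coupling analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
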