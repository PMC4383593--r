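Package: flexstim
Title: Closed-Loop Gaze-Contingent Stimulation Paradigms for fMRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of adaptive (gaze-contingent) fMRI
    stimulation paradigms. Provides an XML experiment-description dialect
    with adaptive constructs (constraints, system variables, stimulus
    actions, transfer functions, dynamic time-based regressors), a
    discrete-time closed-loop scheduler that gates and shifts stimulus
    events on real-time fixation state, dispersion-threshold (I-DT)
    fixation identification, dynamic design-matrix construction with a
    double-gamma haemodynamic response function and an incremental general
    linear model, seeded synthetic gaze and BOLD generators, and offline
    compliance / time-to-valid-trials analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    xml2,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
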