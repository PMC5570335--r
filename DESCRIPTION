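Package: rhasl
Title: Physiological Modelling of ASL Reactive Hyperemia in Calf Muscle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lumped-parameter model of post-occlusive reactive hyperemia in
    calf skeletal muscle as measured by arterial spin labeling (ASL) perfusion
    MRI. A three-segment flow circuit (popliteal artery, arterioles, veins) is
    coupled to two-compartment oxygen transport, red-blood-cell ATP release,
    interstitial adenosine kinetics, and four first-order vasoregulation
    mechanisms (myogenic, shear, ATP, adenosine) acting on arteriolar smooth
    muscle activation. The package provides baseline calibration, stiff ODE
    simulation of cuff-occlusion protocols, response characterization (peak and
    time-to-peak), a synthetic ASL trace generator, and subject-specific
    parameter estimation by bounded nonlinear least squares with the two-step
    healthy schedule and the one-step patient schedule, assessed by reduced
    chi-square.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
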