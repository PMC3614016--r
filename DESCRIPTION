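Package: clampflow
Title: Stopped-Flow FRET Kinetics of Sliding-Clamp Loading, Unloading and
    Holoenzyme Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action simulation and analysis of pre-steady-state
    stopped-flow FRET experiments on the human sliding clamp (PCNA), its
    ATP-driven loader (RFC) and DNA polymerase delta. Builds the stepwise
    loading/unloading/capture reaction network, integrates it to species
    trajectories with a FRET observable, emulates two-syringe mixing,
    instrument dead time, pulse-chase staging and the instrument sampling
    schedules, fits traces to sums of exponentials with dead-time amplitude
    recovery, and infers clamp stoichiometry from amplitude ratios,
    labeled-fraction regression and titration break-points.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
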