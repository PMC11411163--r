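Package: lysim
Title: Population Dynamics and Induction Design for Lysis-Driven
    Therapeutic Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of engineered bacteria that release a
    therapeutic payload through inducible cell lysis. Implements a coupled
    ordinary-differential-equation model of therapeutic and non-lysing
    mutant subpopulations with intracellular toxin accumulation and
    Hill-type induction, closed-form solutions for the mutant fraction
    under lysis-driven selection, a cumulative released-payload proxy,
    growth-curve fitting for plate-reader data (full model fits, Hill
    calibration of the induction response, initial-composition estimation),
    square-wave induction schedule optimisation with takeover-truncated
    payload accounting, model variants (substrate consumption, adaptive
    mutation, chemostat-style dilution with steady-state location), and a
    seeded synthetic plate-reader data generator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
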