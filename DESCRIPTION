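Package: leucokin
Title: Modelling Leucocyte Kinetics After Irradiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative models of leucocyte kinetics following radiation
    exposure: a calibrated blood/lymphoid-organ lymphocyte recirculation
    model, semi-mechanistic myelosuppression models with power-law
    homeostatic feedback (Friberg-type transit chains, bone-marrow/blood
    neutrophil and monocyte models), a two-phase model of radiation-induced
    neutropenia, phenomenological growth-curve fitting with information-
    criterion model selection, dose-covariate screening, two-stage
    individual-based parameter estimation, residual- and cross-validation
    diagnostics, clinical blood-count metrics (lymphopenia grade, NLR, LMR,
    linear-quadratic aberration yield), and a seeded synthetic-cohort
    generator emulating macaque total-body-irradiation kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
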