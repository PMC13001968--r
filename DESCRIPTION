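Package: ecto
Title: Entropy-Initiated Coupled-Trait ODE Modelling of Longitudinal Cohort Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compresses wave-level Likert-scale survey responses into normalized
    Shannon-entropy indices, uses them to initialize a three-state autonomous
    coupled ordinary differential equation system (a primary trait-like state, a
    secondary coupled state, and a latent environmental-stress component), and
    estimates the model's parameters by bounded multistart least squares.
    Includes leave-one-wave-out forecast validation, an uncoupled null model,
    local parameter-sensitivity scans, dynamic-time-warping and regression fit
    metrics, and a seeded synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
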