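Package: adaptsim
Title: Simulation-Based Design and Evaluation of Bayesian Adaptive Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and evaluate multi-arm, multi-stage Bayesian adaptive
    clinical trials by statistical simulation. Supports adaptive stopping for
    superiority, inferiority, practical equivalence and futility; adaptive arm
    dropping; common-control designs with control promotion; and restricted
    response-adaptive randomisation based on posterior probabilities of each
    arm being best. Analysis uses conjugate beta-binomial models for binary
    outcomes (or a normal approximation for continuous outcomes), with a hook
    for user-supplied posterior-draw generators. Includes operating
    characteristics (expected sample sizes, probabilities of conclusiveness,
    superiority, equivalence and futility, arm-selection probabilities,
    estimation errors, ideal design percentage) with bootstrap confidence
    intervals, reproducible parallel batch simulation, calibration of stopping
    thresholds to a target type-1 error using a Gaussian-process surrogate,
    scenario grids for power and error-rate assessment, and a command-line
    interface for config-driven workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
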