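Package: stopstrat
Title: Stop-Signal Task Simulation and Drug-Responder Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates stop-signal task sessions under the independent
    horse-race model with online staircase tracking of the stop-signal
    delay, estimates stop-signal reaction times (SSRT) by the integration
    method with omission adjustment, stratifies patients into drug
    responders and nonresponders against benchmarks defined as fractions
    of the group-level Parkinson's SSRT deficit, and builds and validates
    radial-basis-function support-vector-machine responder classifiers
    with leave-one-out cross-validation, exhaustive (C, gamma) grid
    search, greedy forward feature selection, permutation significance
    tests, ROC curves and benchmark-robustness sweeps.  A synthetic
    cohort generator with planted, configurable responder signal makes
    the full pipeline testable without access to patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
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
    kernlab,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
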