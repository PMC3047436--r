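Package: sphingokinetics
Title: Kinetic Modelling of C16-Branch Sphingolipid Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action kinetic model of the C16-branch of sphingolipid
    metabolism in KLA-stimulated RAW264.7 macrophages: 9 dynamic metabolites,
    4 input lipids and 9 delayed gene inputs driving 25 reactions with 29
    rate constants. Provides dual-condition ODE simulation driven by measured
    time-courses, two-step rate-constant estimation (nonnegative linear least
    squares on discretized derivatives followed by weighted bound-constrained
    nonlinear refinement with initial-condition co-optimization),
    SEM-resampling parameter uncertainty, one-at-a-time parametric
    sensitivity analysis, eigenvalue time-scale classification, and a
    synthetic-data generator for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
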