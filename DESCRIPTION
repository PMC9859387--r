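Package: dcmodel
Title: Diabetes Complications Compartmental Model and Fixed-Step Solvers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the two-compartment diabetes-complications (DC)
    population model: the affine linear system of ordinary differential
    equations for diabetics with and without complications, its closed-form
    solution and exact propagator, five fixed-step numerical integration
    schemes (explicit and implicit Euler, Heun, classical fourth-order
    Runge-Kutta, and a four-step Adams-Bashforth-Moulton
    predictor-corrector), eigenvalue-based stability classification,
    per-scheme amplification-factor diagnostics, and reproducible
    experiment drivers for error tables, step-size and parameter sweeps,
    and incidence scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
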