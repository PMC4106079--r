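Package: hhbif
Title: Stability and Bifurcation Analysis of the Hodgkin-Huxley Model over
    Ion-Channel Conductances
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analyses how the maximal sodium and potassium channel
    conductances shape the local stability of the classic Hodgkin-Huxley
    neuron model.  Provides the model vector field and gate kinetics,
    equilibrium location by bracketed bisection, analytic Jacobians with
    characteristic-polynomial coefficients and the Routh-Hurwitz
    criterion, Hopf bifurcation points located by bisection in a
    conductance, two-parameter stability maps with an ordinary
    least-squares fit of the upper stability boundary, and fixed-step
    Runge-Kutta simulation with fixed-point versus limit-cycle attractor
    classification.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
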