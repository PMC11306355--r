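Package: ntdm
Title: Natural Transform Decomposition Solver for Fractional-Order
    Compartmental Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-analytic series solutions of systems of fractional-order
    ordinary differential equations with constant, linear and bilinear terms
    by the natural transform decomposition method (NTDM), under three
    fractional kernels: Caputo, Caputo-Fabrizio and Atangana-Baleanu-Caputo.
    The transform is applied and inverted analytically, so each solution
    component is an exact finite sum of monomials c * tau^(a + b*mu).
    Includes the five-compartment fractional smoking epidemic model
    (potential, occasional, current, temporarily quit and permanently quit
    smokers) with reproduction-number, stability and sensitivity analysis,
    independent Runge-Kutta and fractional Adams-Bashforth-Moulton
    verification solvers, tidy evaluation tables and ggplot2 plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
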