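Package: liouville
Title: Exact Density Propagation for ODE Models via the Method of
    Characteristics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies uncertainty and variability in ordinary differential
    equation models by propagating the exact probability density of states and
    parameters along trajectories. The transport (Liouville) equation that
    governs the density of an ODE with random initial conditions is solved by
    the method of characteristics: the original ODE is extended by one
    dimension carrying the log-density, so the density at any point and time
    is available at the cost of a single ODE solve. Includes a backward-forward
    procedure for evaluating the density on arbitrary sub-regions (including
    low-probability tails), cell-centered uniform grids with midpoint-rule
    quadrature and marginalization, likelihood computation and grid-profiled
    maximum-likelihood parameter estimation from observed data, a Monte Carlo
    ensemble reference for cross-validation, and built-in gene-expression
    models (autoregulatory positive feedback and the genetic toggle switch).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
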