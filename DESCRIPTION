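Package: qcest
Title: Deuteron Quadrupolar CEST Simulation and Fitting Under Magic-Angle Spinning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits 2H (spin-1) chemical exchange saturation
    transfer (CEST) experiments on rotating solids. Propagates the eight
    spin-1 coherences of an exchanging multi-site system through the
    Liouville-von Neumann equation under magic-angle spinning, with powder
    and radio-frequency inhomogeneity averaging, and produces saturation
    profiles, R_CEST decay rates, quadrupolar T1 estimates from methyl
    three-site jump spectral densities, and grid-search fits of slow-motion
    parameters (flip rates, diffusion coefficients, exchange rates).
    Built-in motional models cover two-site rotameric flips, methyl
    three-site jumps, and diffusion on a sphere in exchange with a bound
    state, the model family used for amyloid fibril side chains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
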