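Package: cmenoise
Title: Steady-State Chemical Master Equation Solutions with Intrinsic and
    Extrinsic Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes steady-state probability distributions of molecule
    numbers in stochastic biochemical reaction networks. Provides a direct
    sparse-linear-algebra solution of the chemical master equation (CME) on a
    truncated state lattice, a rescaled CME for systems with large molecule
    numbers, a modified Gibbs sampler that uses detailed-balance conditional
    distributions along randomly rotated lattice lines to sample
    high-dimensional or multimodal steady states, and a convolution model of
    extrinsic noise. Ships model constructors and configuration files for a
    bistable genetic toggle switch and a growth-coupled T7 RNA polymerase
    positive-feedback circuit, a Gillespie stochastic simulation algorithm as
    an independent oracle, and summary statistics including ON/OFF population
    partitioning rules and a sum-of-squared-deviations distribution distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
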