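Package: hemouq
Title: Lattice Boltzmann Haemodynamics with Polynomial Chaos Uncertainty
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for uncertainty quantification of blood-flow
    simulations in aneurysmal vessels. Provides a D3Q19 two-relaxation-time
    lattice Boltzmann solver with a pressure-responsive elastic wall model,
    pulsatile velocity inlets parameterized by Reynolds and Womersley numbers,
    and two-element Windkessel outlet coupling with Murray-law flow targets;
    wall shear stress risk factors for aneurysm growth and rupture (TAWSS, OSI,
    ECAP, RRT) with clinical threshold masks; a voxelized synthetic vessel
    phantom generator (straight, fusiform-aneurysm and branching geometries);
    and a regression-based polynomial chaos expansion engine with variance-based
    Sobol' sensitivity indices, coefficient-of-variation ratios and a Saltelli
    Monte Carlo cross-check, orchestrated as seeded, resumable campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
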