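Package: pbrsim
Title: Coupled Light, Flow and Growth Simulation for Flat-Panel Photobioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduced-order simulation and parameter-estimation toolkit for
    artificially lit flat-panel photobioreactors running cyanobacterial
    cultures under turbidostat control. Computes multi-domain light
    transmission (two-flux and discrete-ordinates radiative solvers with
    biomass-dependent attenuation), a prescribed divergence-free circulation
    flow, Lagrangian single-cell trajectories with perceived and absorbed
    light histories, Haldane-type photo-growth kinetics with dissolved-oxygen
    and dilution control, photosynthetic-efficiency accounting, and
    multi-start fitters that recover kinetic, optical and LED-calibration
    parameters from synthetic or measured light-staircase campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
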