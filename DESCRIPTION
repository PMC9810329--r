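Package: chromactive
Title: Active Polymer Simulation of Interphase Chromatin with
    Topoisomerase-II Catch-and-Release Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Brownian-dynamics simulation of a confined random multiblock
    copolymer model of interphase chromatin, in which euchromatic (A) and
    heterochromatic (B) beads interact through soft Gaussian excluded
    volume, FENE springs, a short-range heterochromatin affinity, and a
    star-polymer wall potential, and in which Topoisomerase-II activity is
    modelled as a three-state catch-and-release kinetic scheme acting on
    proximal A-bead pairs.  Includes equilibrium model variants (two-state
    schemes, self-avoiding-phantom polymer, non-transient attraction, slab
    geometry), a configuration-analysis suite (grid order-parameter
    distributions with Binder cumulant and skewness, local nematic order,
    heterochromatin-focus segmentation via the gyration tensor, surface
    localization, radial densities, density cross-correlation), a lattice
    mean-field free energy with doublet fraction, extended-XYZ trajectory
    I/O, deterministic synthetic fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
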