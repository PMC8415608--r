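Package: idpevolve
Title: Evolving Liquid-Liquid Phase Separation of Disordered Protein
    Sequences with a Residue-Level Coarse-Grained Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing intrinsically disordered protein sequences
    with enhanced or inhibited liquid-liquid phase separation. Implements a
    residue-resolution bead-spring model with a hydrophobicity-scaled
    Ashbaugh-Hatch pair potential and Debye-Hueckel screened electrostatics,
    a Langevin-dynamics engine for periodic slab direct-coexistence
    simulations, density-profile and binodal analysis with critical-point
    estimation, a genetic algorithm whose fitness is the phase-diagram width
    at fixed temperature, and sequence-space diagnostics (sequence charge
    decoration, chunk shuffling, glycine scanning, pair correlation
    functions, pairwise energy decomposition).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
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
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
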