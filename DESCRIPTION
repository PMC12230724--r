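Package: cdsk
Title: Circular Dichroism Spectroscopy Toolkit for Protein Secondary
    Structure, Fold Recognition and Thermal Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of protein far-UV circular dichroism (CD) spectra.
    Estimates eight secondary-structure fractions (regular and distorted
    alpha-helix, three antiparallel beta-sheet twist classes, parallel
    beta-sheet, turn, and others) by deconvolving a CD spectrum against a
    composition-dependent basis-matrix model, and trains that model from a
    reference set of proteins with known structures.  Computes the same
    eight components directly from PDB/mmCIF structures via a
    hydrogen-bond-based secondary-structure assignment with beta-sheet
    twist classification.  Additional tools: nearest-neighbour protein
    fold recognition in secondary-structure space, ordered/disordered
    classification of spectra from wavelength triplets, two-state
    Gibbs-Helmholtz fits of thermal denaturation profiles, far-UV
    extinction-coefficient calculation from sequence, and seeded synthetic
    data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
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
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
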