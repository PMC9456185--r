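Package: hostguest
Title: Host-Guest Inclusion Complex Thermodynamics and Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for cyclodextrin host-guest inclusion complexes.
    Fits Higuchi-Connors phase-solubility diagrams, classifies A_L-type
    behaviour, computes apparent stability constants, and infers enthalpy,
    entropy and Gibbs free energy of complexation by Van't Hoff regression.
    Provides trajectory-level structural descriptors for macrocyclic hosts
    (superposed RMSD, radius of gyration, host-guest atom contacts, rim
    oxygen distances and their Boltzmann-inverted 2D free-energy landscape),
    radial distribution functions with first-minimum coordination numbers,
    and MM/PBSA energy-component aggregation across replicate simulations.
    Includes synthetic-data generators with known ground truth for every
    analysis stage, readers and writers for the plain-text formats involved
    (CSV/TSV tables, multi-model PDB, XYZ with JSON topology sidecars), and
    tidy/ggplot2 methods for all result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
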