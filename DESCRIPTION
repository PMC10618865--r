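Package: sympatree
Title: Age-Range Correlation and Sympatry Analysis for Sister Species
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for testing geographic modes of speciation from a
    time-calibrated phylogeny and species range maps. Extracts sister
    species pairs, computes area-true range overlap and range symmetry
    indices on a spherical grid, classifies pairs as sympatric or
    allopatric, regresses overlap and symmetry on node age (age-range
    correlation), contrasts ecological traits between classes with
    Welch's t-tests, and measures phylogenetic signal with Blomberg's K,
    Fritz's D, phylogenetic generalized least squares under an
    Ornstein-Uhlenbeck error model, and (partial) Mantel tests. Includes
    a synthetic-data generator that simulates birth-death trees, range
    evolution under sympatric, vicariant and peripatric speciation with
    post-speciation drift, and Brownian and Markov trait evolution, so
    the full pipeline is testable without external range databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
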