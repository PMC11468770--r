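Package: neuronkit
Title: Desk-Scale Toolkit for Collaborative Neuron Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-neuron reconstructions and the
    collaborative proofreading process that produces them. Reads and writes
    SWC/ESWC neuron trees and validates the quasi-binary tree convention;
    computes global morphometry, length-based agreement between
    reconstructions, bidirectional consistency and topological-height
    statistics across reconstruction stages; detects soma candidates in 3-D
    image volumes with a distance-transform pipeline and axonal boutons from
    joint intensity/radius profiles; prepares image/mask patch pairs for
    pluggable branching- and terminal-point verifiers; scores image quality
    with non-negative matrix factorisation; and simulates the multi-annotator
    cross-validation protocol on synthetic ground-truth neurons so every
    analysis is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
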