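Package: flynet
Title: Tracking, Touch Classification and Social Network Analysis for
    Groups of Walking Flies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for studying social behaviour in groups of
    walking fruit flies filmed from above: constant-count multi-animal
    tracking built on bipartite node duplication, Hungarian assignment and
    EM splitting of merged detections; supervised classification of
    head-to-tail touch events from 22 trajectory features; construction of
    directed weighted social interaction networks and their quantification
    by nine network parameters; averaging of node-unaligned networks by
    graduated-assignment graph matching; and the rank-based group
    comparison statistics used with such parameters. Includes a synthetic
    arena simulator that renders videos with exact ground truth so every
    stage can be validated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
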