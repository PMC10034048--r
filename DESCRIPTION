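Package: hinge3
Title: Identification of Cortical 3-Hinge Gyral Folding Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects 3-hinge gyral folding patterns (triple junctions of gyral
    crests) on cortical surface meshes from per-vertex morphometry. Provides
    readers and writers for FreeSurfer binary surface/morph and GIfTI formats,
    a seeded synthetic cortical-sheet generator with planted ridge networks and
    ground-truth hinge junctions, spherical expansion of hinge vertices into
    binary region labels, k-nearest-neighbour feature aggregation with
    fixed-size blocking for network input, a squeeze-and-excitation U-net
    segmenter for hinge regions implemented on BLAS matrix arithmetic, weighted
    mean-shift extraction of hinge centroids, and evaluation utilities
    (precision/recall/F1, centroid prediction error, accuracy-gender
    correlation) with tidy tabular outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    RANN,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
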