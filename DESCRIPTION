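Package: hicregnet
Title: Cross-Cell-Type Hi-C Contact Prediction and Variant-to-Subnetwork Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts high-resolution (5 kb) Hi-C contact counts in new cell
    types from one-dimensional epigenomic signals using locally trained
    random-forest regression over 1 Mb segments, calls significant long-range
    interactions with a distance-stratified binomial test, detects TADs with
    the directionality index, and interprets non-coding variants by linking
    them through predicted loops to genes and propagating their effect over
    cell-type-specific molecular networks via Laplacian and insulated-heat
    graph diffusion, diffusion-state distance, and tree-guided multi-task
    spectral clustering. Includes synthetic-data generators with planted
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
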