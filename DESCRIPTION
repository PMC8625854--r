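Package: stomaCount
Title: Two-Stage Neural Detection and Stereological Counting of Stomata
    in Epidermal Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects stomatal complexes on calibrated micrographs of leaf
    epidermal imprints and reports stomatal density in pores per square
    millimetre. A first-stage convolutional network regresses a Gaussian-peak
    heatmap of stomatal locations; candidate centers extracted from the
    blurred, thresholded heatmap are verified by a second-stage window
    classifier that rejects imprint artifacts such as air bubbles and thorn
    cells. Confirmed centers are counted inside an unbiased stereological
    counting frame (inclusionary top/right borders, exclusionary bottom/left
    borders) so that exhaustive tiling counts every stoma exactly once.
    Includes a seeded synthetic micrograph generator with red-painted
    annotation images for training and benchmarking, red-annotation
    conversion to center sets and Gaussian target heatmaps, image tiling,
    center-matching evaluation (precision, recall, accuracy), and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
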