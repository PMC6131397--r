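Package: follidetect
Title: Automated Detection and Counting of Primordial Ovarian Follicles in
    Whole-Slide Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting and counting primordial
    ovarian follicles (PMF) on digitised histological slides: section
    isolation by contour detection on a binarised low-resolution slide,
    construction of a balanced and augmented patch training set from point
    annotations, a small VGG-style convolutional patch classifier trained
    with mini-batch Adadelta, half-overlap sliding-window detection with
    greedy non-maximum suppression, hard-negative-mining retraining, and
    recall/precision bookkeeping with an operator-focus correction. A
    seeded synthetic-slide generator with known ground truth makes every
    stage testable without access to scanner data.
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
    png,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml,
    EBImage
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
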