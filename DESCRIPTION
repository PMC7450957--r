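Package: mitedamage
Title: Automated Quantification of Spider Mite Feeding Damage on Plant Rosette Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies chlorotic feeding damage caused by the two-spotted
    spider mite (Tetranychus urticae) on whole Arabidopsis rosette scans.
    Implements a machine-learning pixel-classification pipeline (random-forest
    classifier over a multi-scale image feature stack), connected-component
    cluster-size noise filtering calibrated on control rosettes, and a
    control-rosette error correction, together with two comparator
    segmentation strategies (two-stage colour-plane thresholding and
    grid-average green-deficiency detection), an emulator of the manual
    grid-counting standard, and the agreement-statistics suite used to compare
    methods (Bland-Altman bias and limits of agreement, coefficient of
    repeatability, Lin's concordance correlation, Spearman correlation,
    genotype damage quotients). A seeded synthetic rosette-scan generator with
    per-pixel ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
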