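Package: ophiocount
Title: Segment-and-Count Quantification of Brittle Stars in Seabed Mosaics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify brittle stars (Ophiuroidea) in 2D seabed
    mosaic imagery by a segment-and-count approach: a pyramid-pooling
    convolutional segmentation network trained on sliding-window patches
    with an additive Jaccard+Focal loss, followed by a morphological
    counting workflow (opening, small-blob removal, Euclidean distance
    transform, peak-seeded watershed) and pixel-level (IOU) plus
    instance-level (strict and forgiving) evaluation. Includes a
    synthetic benthic scene generator with exact polygon ground truth in
    both full-shape and disc-only annotation variants, underwater image
    enhancement pre-processing (gamma correction, CLAHE, percentile
    stretch), and an end-to-end experiment driver.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
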