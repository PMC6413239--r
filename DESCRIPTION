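Package: polarseg
Title: Polar-Body Detection in Oocyte Micrographs by Inception U-Net
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and localizes the polar body in brightfield oocyte
    micrographs, a prerequisite for automated micromanipulation (somatic
    cell nuclear transfer, intracytoplasmic sperm injection, polar-body
    biopsy). Detection is cast as semantic segmentation: a
    contraction-expansion convolutional network built from nine
    inception-style multi-branch modules maps a grayscale micrograph to a
    per-pixel polar-body probability map, trained with a weighted
    combination of soft Dice loss and pixel-wise binary cross-entropy.
    Candidate regions are then filtered by a region-level non-maximum
    suppression with max-probability and minimum-area constraints, and the
    winning region's pixel-location mean gives the polar-body centroid.
    Includes a synthetic oocyte-scene generator (cytoplasm, zona pellucida,
    micropipettes, defocus, elastic deformation) producing paired
    image/mask data, paired geometric data augmentation (rotation,
    flipping, elastic transform), a seeded training loop, and an evaluator
    implementing the 10-pixel centroid-distance correctness criterion.
    The network engine (convolution, pooling, transposed convolution,
    batch normalization, Adam) is implemented in R on BLAS matrix
    products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
LinkingTo: Rcpp, RcppArmadillo
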