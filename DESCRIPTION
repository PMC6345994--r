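Package: hyperclass
Title: Label-Free Cell Classification from Hyperspectral Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for pixel-wise classification of cell types in label-free
    hyperspectral transmission microscopy images. Provides flat-field correction
    and band selection for hyperspectral stacks, spectrum-wise k-means clustering
    for information reduction into cluster images, multi-scale morphological
    feature extraction (Hessian, Laplacian, local standard deviation, circular
    standard deviation of gradient orientations), a random forest classifier with
    single-feature and feature-difference split rules trained by entropy
    reduction, pixel-wise and object-wise evaluation with leave-one-out cross
    validation, a seeded generator of synthetic hyperspectral scenes with ground
    truth for testing, and optical quality metrics (Hopkins two-point lateral
    resolution, illumination stability).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
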