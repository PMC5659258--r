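Package: tomocell
Title: Cell Detection and Mesoscale Anatomy Quantification in X-Ray
    Microtomography Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying mesoscale neuroanatomy in 3D X-ray
    microtomography (microCT) image volumes. Provides voxel-level
    classification into cell / vessel / background probability maps using
    multi-scale image features and a random forest, greedy matching-pursuit
    detection of cell centroids by FFT correlation with a spherical
    template, per-cell size estimation, morphological vessel and axon
    segmentation, k-nearest-neighbour density estimation over a 3D grid,
    cell-to-cell and cell-to-vessel distance statistics, an evaluation
    suite (f-beta scores, centroid matching, SNR, effective-resolution
    estimation, hyperparameter grid search), block-wise processing of
    volumes larger than memory, and a synthetic phantom generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    graphics,
    stats,
    tiff,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
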