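Package: visionet
Title: Vision-Related Brain Network Connectivity and Morphometry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for resting-state functional connectivity of
    vision-related brain networks (primary visual, higher visual and
    visuospatial) together with voxel-based morphometry of gray-matter maps.
    Implements temporal band-pass filtering, spatial Gaussian smoothing and
    motion-based quality control; voxel-wise two-sample statistics with
    threshold-free cluster enhancement (TFCE) and permutation-based
    family-wise error correction; ROI time-series extraction, Fisher
    z-transformed network connectivity matrices with FDR-controlled group
    comparison and clinical correlation; and a synthetic-cohort generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    withr,
    yaml,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
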