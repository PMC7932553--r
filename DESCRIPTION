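Package: nccv
Title: Automated Quantification of Intradermal Cystine Crystals from
    Reflectance Confocal Microscopy Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies crystal-like bright objects in in-vivo
    reflectance confocal microscopy (RCM) skin Z-stacks.  Per-slice
    segmentation selects small bright objects with a robust intensity
    threshold, detects dermal papillae as large smooth structures, and
    excludes candidates overlapping them.  Depth-resolved normalized
    crystal-area profiles, 3D reconstruction of isolated crystals within a
    papillary-dermis slice band, and a per-stack normalized confocal crystal
    volume (nCCV, um^3) summary statistic are computed from the surviving
    regions.  A synthetic stack simulator with exact voxel ground truth, a
    statistics layer (per-slice group comparison with Sidak familywise
    control, Welch t-test, ROC/AUC with bootstrap confidence intervals,
    standardized-predictor regression associations, repeatability CV, and
    pediatric clinical unit helpers), and command-line entry points make the
    whole pipeline testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
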