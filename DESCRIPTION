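Package: nephroseg
Title: Two-Stage Coarse-to-Fine Kidney and Kidney Stone Segmentation in Unenhanced CT
Version: 0.1.0
Authors@R:
    person("Nephroseg", "Developers", email = "nephroseg@example.org",
           role = c("aut", "cre"))
Description: A dependent (coarse-to-fine) two-stage pipeline for segmenting
    kidneys and detecting kidney stones in unenhanced abdominal CT volumes.
    Stage one localizes the kidneys at reduced resolution with a compact 3D
    U-Net; stage two segments kidney and stone finely inside per-kidney
    regions of interest derived from the coarse prediction. Includes
    Hounsfield-unit preprocessing, z-spacing harmonization, sliding-window
    cube clipping with overlap-averaged stitching, labeled-cube augmentation,
    an AdamW training recipe with a combined soft-Dice and cross-entropy
    loss, stone-size-stratified evaluation, NIfTI-1 input/output, and a
    seeded synthetic CT phantom generator so the whole pipeline is trainable
    and testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
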