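Package: spinemask
Title: Two-Phase Semantic and Instance Segmentation of Whole-Spine MRI Label Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for converting multi-class semantic segmentations of
    sagittal whole-spine MR images into per-vertebra instance masks. A
    semantic mask covering 14 spinal structures (ten vertebral
    substructures, intervertebral disc, spinal canal, spinal cord and
    sacrum) is turned into an instance mask by sliding fixed-geometry
    cutouts over the vertebral-body centers, predicting relative
    above/center/below labels per cutout, scoring each vertebra's repeated
    appearances by their mutual agreement, and fusing them in
    consistency order. Includes the accompanying label-map post-processing
    rules, multi-source reference-annotation merging, a synthetic spine
    phantom generator for fully reproducible testing, and an evaluation
    suite with Dice, average symmetric surface distance and panoptic
    quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
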