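Package: alpdnet
Title: Background-Suppressed Multi-Scale Detection of Wild Licorice in UAV
    Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A single-stage, anchor-free object-detection framework for
    locating and classifying three visually similar Glycyrrhiza (licorice)
    species in UAV imagery of arid rangeland. Implements a ResNet34-derived
    backbone with an adaptive background-suppression module (channel-token
    multi-head self-attention plus coordinate-aware spatial gating) in every
    residual block, a lightweight grouped dilated-convolution multi-scale
    module after every stage, and a progressive feature-fusion neck built
    from weighted self-attention fusion units. Ships the complete data
    pipeline (tiling of large frames, YOLO-format label I/O, stratified
    splitting, box-aware augmentation), a synthetic vegetation-scene
    generator for end-to-end testing, a seeded SGD trainer with early
    stopping, detection metrics (precision, recall, mAP50, mAP50-95,
    F1-confidence and precision-recall curves), Grad-CAM saliency maps, and
    a per-layer FLOP accountant for architecture cost audits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    grDevices,
    graphics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
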