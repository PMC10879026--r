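Package: rbcdetect
Title: Red Blood Cell Detection in Blood-Smear Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for detecting and counting red blood cells in grayscale
    blood-smear microscopy images. Provides edge-preserving bilateral
    filtering with a radial-gradient-index (RGI) blob score,
    threshold-plus-morphology segmentation with connected-component cell
    counting, a compact region-proposal convolutional detector (anchors,
    box-regression decoding, non-maximum suppression, RoI pooling and a
    multi-task loss) trained on CPU, post-detection scoring by RGI and
    box-counting fractal dimension, and IoU-based detection evaluation with
    holdout and k-fold protocols. A synthetic blood-smear generator with
    exact ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    jpeg,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
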