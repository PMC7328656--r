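Package: phenomask
Title: Detection, Counting, and Measurement of Reproductive Structures on
    Herbarium Sheets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fine-grained phenological annotation of digitized
    herbarium specimens. Implements the three annotation regimes used to
    train instance-segmentation models on herbarium sheets (3x3-pixel point
    masks, Otsu-thresholded partial masks inside 100x100-pixel windows, and
    full hand-drawn polygon masks), a COCO-dialect JSON reader/writer, a
    pluggable instance-segmentation contract with a classical rule-based
    baseline detector, and the full evaluation suite: counting precision,
    average precision at IoU > 50%, size-wise AP, detection/confusion
    probability matrices, and bounding-box-diagonal size measurement with
    pixel-to-centimeter calibration. A synthetic sheet generator with exact
    ground-truth masks and a parametric prediction-perturbation model make
    the whole pipeline testable end to end without any trained network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
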