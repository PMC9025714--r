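Package: cherryfill
Title: Flood-Fill Background Extraction and Detection Dataset Tools for Fruit Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Edge-seeded, floating-range flood-fill background extraction for
    fruit images, together with the dataset-preparation pipeline used around it
    in quality-grading object detection: right-angle augmentation of images and
    bounding boxes, Pascal VOC (labelimg dialect) and YOLO annotation
    conversion, grouped and stratified train/test splitting, and
    precision/recall/average-precision evaluation. Includes a synthetic
    cherry-scene generator with exact ground-truth masks and boxes so the whole
    pipeline is testable without a real fruit dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    xml2,
    yaml,
    jsonlite,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jpeg,
    optparse
Config/testthat/edition: 3
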