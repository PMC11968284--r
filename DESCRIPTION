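Package: circlefuse
Title: Weighted Circle Fusion and Evaluation for Circle-Based Detection
    on Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a whole-slide glomerulus detection
    pipeline built on circle representations. Provides exact circle
    intersection-over-union geometry, non-maximum suppression and Soft-NMS
    for redundancy removal, the weighted circle fusion (WCF) ensemble with
    model-consensus and confidence thresholds, half-overlap slide tiling
    with local-to-global coordinate mapping, a circle-IoU mAP/average-recall
    evaluator, QuPath-compatible GeoJSON and CSV interchange, and a
    synthetic multi-detector benchmark generator so the full pipeline is
    testable without trained networks or slide images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
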