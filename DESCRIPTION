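Package: pblnet
Title: Per-Tooth Periodontal Bone Loss Detection in Panoramic Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-phase framework for detecting periodontal bone loss (PBL)
    per tooth in panoramic dental radiographs. Aggregates multi-annotator
    tooth labels (majority vote) and lesion masks (pixel union), trains a
    U-shaped network to segment the teeth region and post-processes its mask
    (hole filling, convex hull, crop, z-score), pre-trains a lesion segmenter
    with pixel focal loss, transfers its encoder into generalist and
    premolar/molar specialist multi-label tooth classifiers trained with a
    focal plus auxiliary label co-occurrence loss, ensembles their
    predictions, selects operating points against clinician reference
    performance, and evaluates with the standard tooth-level metric suite.
    Includes a synthetic panoramic-radiograph generator with simulated
    annotators so the whole pipeline is trainable and testable at desk scale,
    plus Grad-CAM visualisation of classifier evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
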