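Package: ropscreen
Title: Smartphone Fundus Video Screening for Retinopathy of Prematurity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a smartphone-video screening
    pipeline for retinopathy of prematurity (ROP). Locates the circular
    magnifier field in each video frame with a circular Hough transform
    searched over a lens-derived radius range, crops and resizes the fundus
    image, ranks frames with a trainable quality classifier, classifies
    frames for ROP with a sensitivity-weighted classifier calibrated by
    temperature scaling, and aggregates the top-ranked frame calls into a
    patient-level decision under the any-positive rule. Includes a
    ground-truthed synthetic fundus video generator so the whole pipeline is
    exercisable without clinical data, plus the evaluation statistics used
    in reader studies (confusion metrics, AUROC, normal-approximation
    confidence intervals, stratified splits).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
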