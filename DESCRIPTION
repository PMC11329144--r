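Package: bruitlearn
Title: Contrastive Learning for Arteriovenous Graft Bruit Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects arteriovenous graft (AVG) stenosis from blood-flow sounds
    (bruits) recorded at the vascular access of hemodialysis patients. Recordings
    are weakly labeled from percutaneous transluminal angioplasty (PTA) timelines,
    converted to log-mel spectrograms and classified by a CNN14-style convolutional
    network whose initial weights can be learned from unlabeled recordings by
    InfoNCE contrastive pre-training on random audio crops. Includes a seeded
    synthetic bruit simulator so the whole pipeline is testable without clinical
    audio, stratified cross-validated evaluation with confusion-matrix metrics and
    ROC/AUC, an exhaustive-search auditor for printed metric tables, and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
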