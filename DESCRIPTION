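Package: dentsense
Title: Stimulus-Locked Trigeminal Calcium Imaging, ISH Registration and
    Jaw-Reflex Quantification
Version: 0.1.0
Authors@R:
    person("dentsense", "maintainers", email = "maintainers@dentsense.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for in vivo trigeminal ganglion calcium
    imaging of tooth-innervating mechano-nociceptors and the associated
    reflex physiology. Provides inter-frame motion correction (translation
    rough pass then affine fine-tuning with a mean-squares metric and
    regular-step gradient descent), neuropil-corrected dF trace extraction
    with area-under-curve and Feret-diameter morphometrics, stimulus-locked
    responder classification including the 2-of-3 electrical-round rule,
    alignment of post hoc in situ hybridization images to in vivo guidepost
    images (second-order polynomial initialization plus multiresolution
    Demons refinement), ROI-based immune-cell fluorescence quantification,
    EMG reflex metrics (band-pass, leaky integration, latency, duration and
    peak-to-peak) and jaw-opening kinematics from two-keypoint tracks. A
    synthetic-data generator with known ground truth makes every stage
    testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
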