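Package: neurovasc
Title: Neurovascular Coupling Analysis for Awake Two-Photon and Photometry Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for relating neural activity to cerebral arteriole diameter
    in awake, behaving mice. Implements vessel lumen diameter extraction from
    two-photon image stacks by full-width-at-half-maximum profiling (pial
    vessels) and Thresholding in Radon Space (penetrating arterioles),
    red-blood-cell velocimetry from linescan space-time images via the Radon
    transform, treadmill locomotion binarization and locomotion-triggered
    averaging, local field potential band-power analysis, fiber-photometry
    photobleaching and hemoglobin-absorption correction, and linear
    mixed-effects treatment comparisons with animal-level random intercepts.
    A synthetic-data generator emulates every recording modality with known
    ground truth so each stage of the pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    lme4,
    lmerTest,
    jsonlite,
    tiff,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
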