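Package: nirspipe
Title: Preprocessing and Group Analysis of Block-Design Prefrontal fNIRS Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of 8-channel, dual-wavelength (760/850 nm)
    functional near-infrared spectroscopy recordings acquired during block-design
    tasks: optical-density conversion, sliding-window motion-artifact flagging,
    zero-phase Butterworth band-pass filtering, modified Beer-Lambert conversion
    with age-adjusted differential pathlength factors, HRF-convolved GLM
    activation betas, prestimulus-baseline Cohen d, pairwise channel
    coactivation, and pre/post paired group inference with Benjamini-Hochberg
    correction, brain-behavior correlation and sensitivity analyses. Includes a
    synthetic-data generator that emulates the block designs, physiological
    noise and planted pre-to-post effects so every stage is testable without
    proprietary acquisition files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
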