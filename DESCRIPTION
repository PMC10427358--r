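Package: perfusense
Title: Real-Time Spectrofluorometric Biomarker Monitoring for Machine Perfusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A software toolkit for real-time quantification of perfusate
    biomarkers (flavin mononucleotide, NADH, creatinine) during ex situ
    organ machine perfusion. Provides a synthetic instrument and perfusion
    simulator in place of hardware, dark-frame-corrected streaming
    quantification with linear fluorescence calibration and 3-sigma limits
    of detection, a flow-injection colorimetric assay model for creatinine
    in waste dialysate, and clinical graft-assessment analytics: trajectory
    AUC, cohort reference bands, deviation classification, exponential
    transaminase-decay fits and outcome correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
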