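Package: trackdose
Title: Real-Time Dose Reconstruction for MLC-Tracked Step-and-Shoot Radiotherapy
Version: 0.1.0
Authors@R:
    person("trackdose", "developers", email = "trackdose@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator and reconstruction library for
    multi-leaf-collimator (MLC) tracked step-and-shoot prostate
    radiotherapy. Builds a digital pelvic phantom with target and
    organ-at-risk volumes, generates step-and-shoot IMRT plans and
    pre-calculated dose influence matrices from a documented synthetic
    pencil-beam-like kernel, simulates asynchronous delivery streams
    (MLC aperture reports and machine states) in static, conventional
    and tracked modes under intrafraction prostate motion with
    localisation latency, reconstructs the actually delivered dose per
    MLC aperture, and analyses target coverage and organ-at-risk dose
    through dose-volume histograms, Dx/Vx metrics and non-tumour
    integral dose. Batch sweeps cover interfractional offset grids and
    pitch/roll rotation grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
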