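Package: gazeid
Title: Eye-Movement Biometric Identification from Jumping-Point Gaze Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end pipeline for identifying people from the dynamics of
    their eye movements recorded while they follow a jumping-point stimulus.
    Reads 1000 Hz gaze recordings in degrees of visual angle, cuts 303-sample
    event-aligned windows around each stimulus jump (saccadic latency, saccade,
    fixation), derives seven 100-element dynamic time series per segment
    (velocity, acceleration, jerk, their point-to-point percentage changes, and
    the DFT amplitude spectrum of velocity) plus a 16-value statistical summary,
    and classifies identities with a two-layer LSTM network or a dense network
    implemented natively. Evaluation uses Leave-One-Session-Out cross-validation
    with per-user score-level probability fusion, reporting accuracy, macro F1
    and Cohen's kappa. Includes a parametric oculomotor simulator (main-sequence
    saccades, latency, fixation noise, blinks) so the whole pipeline is testable
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
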