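Package: nanopulse
Title: Event Detection and Feature Extraction for Nanopore Current Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing of resistive-pulse (nanopore) ionic-current
    recordings: adaptive moving-window baseline tracking with iterative
    event decoupling, double-threshold (hysteresis) pulse detection with
    track-back, boundary refinement by second-order difference extrema and
    rise-time correction, and per-event feature extraction (dwell time,
    blockade amplitude, peak, event charge deficit). Includes a synthetic
    trace generator with ground truth, population statistics with
    Gaussian-mixture peak counting on the event-charge-deficit
    distribution, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    mclust,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
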