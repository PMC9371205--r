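Package: swimlaps
Title: Swimming Activity Recognition and Lap Timing from a Sacral IMU
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for monitoring pool swimming with a single
    six-channel inertial measurement unit worn on the sacrum. Preprocesses
    280 Hz accelerometer/gyroscope recordings (zero-phase Butterworth
    low-pass, downsampling to 50 Hz, per-channel standardization), classifies
    every 0.02 s frame into eight activity classes (four stroke techniques,
    wallpush, underwater, turn, rest) with a stacked bidirectional LSTM
    network trained by backpropagation through time with ADAM, cleans the
    predicted label sequence with a minimum-duration segment filter, derives
    typed lap times (start/middle/end) from class transitions, and quantifies
    agreement against reference timings (bias, typical error of measurement,
    Bland-Altman limits, mean absolute percentage error). Includes a
    synthetic swimming-session simulator so the full pipeline is testable
    without access to pool recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
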