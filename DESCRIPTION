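Package: phaselock
Title: Closed-Loop EEG Alpha-Phase Prediction and Phase-Locked Triggering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulator of a real-time closed-loop EEG system that
    targets the instantaneous phase of occipital alpha oscillations (8-13 Hz).
    Implements the online pipeline (decimation to 500 Hz, sliding 500-sample
    window, demeaning, two-pass FIR bandpass, edge trimming, 85-sample
    autoregressive forward prediction by Yule-Walker or adaptive least-mean-
    square fitting, Hilbert-transform phase at time-zero, and phase-crossing
    trigger emission) together with the circular-statistics evaluation suite:
    phase-locking factor, Rayleigh Z with its large-sample critical value,
    two-sample Watson U-squared, circular means and recentering, and the
    phase-triggered response. Includes a seedable synthetic alpha-EEG
    generator with known ground-truth phase so the whole loop is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
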