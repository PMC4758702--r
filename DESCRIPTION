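Package: smrbci
Title: Co-Adaptive Sensorimotor-Rhythm BCI Simulation and Resting-State
    Performance Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale, closed-loop simulation of a fully automatic
    co-adaptive motor-imagery brain-computer interface driven by the
    sensorimotor rhythm (SMR). Generates synthetic multichannel EEG with
    1/f background, subject-specific mu/beta oscillations and
    class-dependent event-related desynchronization (ERD); implements the
    signal path (Butterworth band-pass, Chebyshev low-pass with
    downsampling, Laplacian derivations, log band-power features), common
    spatial patterns with automatic filter-count selection, plain and
    shrinkage linear discriminant analysis with three adaptation schemes
    (supervised class-mean, adaptive inverse covariance, unsupervised
    pooled-mean bias tracking), rate-control cursor feedback with a
    positively biased mode, the three-phase seven-run session protocol
    with two retraining points, a resting-state spectral predictor of BCI
    performance (smoothed PSD at Laplacian C3/C4 minus a fitted 1/f noise
    floor), and the accompanying statistical analyses (binomial chance
    thresholds, ERD/ERS time courses, cohort accuracy summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
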