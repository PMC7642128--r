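Package: mierd
Title: Motor-Imagery EEG Simulation, Wavelet Band Analysis, and ERD/ERS
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for left- versus right-hand motor-imagery
    electroencephalography (EEG). Generates labelled synthetic sessions with
    mu (~10 Hz) and beta (~20 Hz) sensorimotor rhythms, contralateral
    event-related desynchronization (ERD) and ipsilateral synchronization
    (ERS) at C3/C4, 1/f background noise and optional artifacts; decomposes
    signals with a three-level Daubechies-6 Mallat pyramid and reconstructs
    the 6.25-25 Hz band (D2+D3); estimates power spectral densities by the
    periodogram; quantifies ERD/ERS as 100*(E-R)/R from band energies before
    and after the imagery cue; and trains compact convolutional and LSTM
    classifiers on channel-by-time epochs with stratified 5-fold
    cross-validation. Includes EDF and epoched-container I/O and an
    end-to-end, seed-deterministic pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
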