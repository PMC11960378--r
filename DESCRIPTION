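Package: swdnet
Title: Detection of 3 Hz Spike-Wave Discharges in Scalp EEG with a Residual
    CNN and Bidirectional GRU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting typical absence seizures (generalized 3 Hz
    spike-and-slow-wave discharges) in multichannel scalp EEG. Provides EDF
    input/output with seizure-interval annotations, 10-20 channel
    canonicalization, anti-aliased resampling, an order-12 Butterworth
    band-pass realized in second-order sections, short-time Fourier
    spectrogram features combined with raw-signal windows, a residual CNN
    encoder with a bidirectional GRU sequence-labeling head (plus three
    simpler comparison architectures), focal-loss training with Adam, and
    event-based scoring by temporal overlap (TPR/TNR/PPV/NPV/F1). A seeded
    synthetic-EEG simulator generates annotated absence-epilepsy recordings
    (posterior-dominant background, frontal-dominant spike-wave bursts,
    blink/EMG/ECG artifacts, realistic class imbalance) so the whole pipeline
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
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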