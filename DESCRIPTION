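Package: semgfgr
Title: Surface EMG Finger-Gesture Recognition with Wavelet Scalograms and a Compact CNN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and classification pipeline for multichannel surface
    electromyography (sEMG) finger-gesture recognition. Simulates a wireless
    six-channel sEMG acquisition chain (instrumentation gain, second-order
    band-pass conditioning, 16-bit quantization, sensor noise), segments trials
    with a fixed-length sliding window, transforms windows into continuous
    wavelet transform (CWT) scalograms under six mother-wavelet families
    (Mexican hat, Gaussian, complex Morlet, Shannon, frequency B-spline,
    complex Gaussian), classifies eight finger gestures with a compact
    five-stage convolutional network with a global-average-pooled head, and
    evaluates runs with accuracy-rate statistics (AR, MAR, SD-AR) including
    kernel-size and mother-wavelet model-selection grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
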