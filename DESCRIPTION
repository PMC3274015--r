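Package: gyrowave
Title: Wavelet-Based Feature Extraction and Neural-Network Classification of
    Leg-Motion Gyroscope Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-channel wearable gyroscope recordings of repetitive
    leg motions (sensor voltage mapping, saturation, 8-bit quantization,
    downsampling, fixed-length segmentation), extracts discrete-wavelet-transform
    features from the signal segments (sub-band energy distribution ratios,
    normalized coefficient means and variances, and their combinations across
    the Haar, Daubechies, Symlet, Coiflet, biorthogonal, reverse-biorthogonal
    and discrete Meyer families), and classifies motions with a three-layer
    feed-forward network trained by the Levenberg-Marquardt algorithm,
    including hidden-layer size search, train/test splitting, decomposition
    level and wavelet-family scans, and repeated-run confusion statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
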