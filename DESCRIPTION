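Package: fuzzytrack
Title: Adaptive Fuzzy External/Internal Correlation Models for Tumor Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Correlation models for real-time respiratory tumor tracking from
    external surface surrogates. Implements first-order Takagi-Sugeno fuzzy
    inference systems seeded by subtractive clustering (SUB-FIS) or fuzzy
    C-means clustering (FCM-FIS), and an adaptive neuro-fuzzy system (ANFIS)
    trained by hybrid least-squares/gradient learning, mapping 9-channel
    external marker motion to 3-D internal tumor position. Includes
    training-time model selectivity on a temporal 75/25 holdout,
    intra-treatment model updating by rebuild on accumulated imaging data,
    a synthetic quasi-periodic respiratory-motion simulator, and targeting
    error evaluation (3-D RMSE, cohort median/IQR, empirical CDFs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
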