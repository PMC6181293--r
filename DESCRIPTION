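Package: cinevoc
Title: Classifying Films from Crowd-Emitted VOC and CO2 Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for predicting a film's age classification
    from volatile organic compound (VOC) and CO2 mixing-ratio time series
    measured in cinema exhaust air. Implements a well-mixed one-box
    mass-balance emission model to detrend per-person traces, a peak-based
    18-value featurization of the residual series, a leave-one-film-out-
    per-class random-ensemble evaluation with one-vs-rest ROC and
    precision-recall scoring, a film-level label-permutation significance
    test, and a synthetic-study generator that emulates the measurement
    campaign's statistical structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
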