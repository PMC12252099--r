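Package: imugrf
Title: Synchronizing Shank IMU and Force-Plate Streams and Predicting Running
    Vertical Ground Reaction Forces with Wavelet and Feed-Forward Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for aligning asynchronously recorded wearable-sensor and
    instrumented-treadmill data during running and for estimating the vertical
    ground reaction force (vGRF) waveform from a single shank-mounted inertial
    measurement unit (IMU). Implements the sliding time window synchronization
    (STWS) algorithm that matches windows of consecutive stride durations
    between the two streams by minimum RMSE, gait-event detection for both
    streams (coronal angular-velocity minima for IMU toe-off, a 50 N vGRF
    threshold for the force plate), stance-phase extraction with 101-point
    spline normalization and body-weight scaling, single-hidden-layer wavelet
    (Morlet) and sigmoid feed-forward neural network regressors trained by
    Adam with L2 regularization, agreement statistics (CMC, RMSE, NRMSE, MAPE,
    R-squared, Bland-Altman limits of agreement), and a seeded synthetic gait
    generator that emulates treadmill running trials with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
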