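Package: behavtrace
Title: Complementary Wearable and Premise-Embedded Tracing of Human Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracing human activity from complementary wearable and
    premise-embedded sensors. Implements Horn-Schunck optical flow with
    silhouette detection and eight-bin flow-direction histograms, the
    accelerometer preprocessing chain (offset removal, smoothing, per-subject
    normalization, unit-range mapping, decimation), fused k-nearest-neighbor
    activity recognition with a leave-one-out k selection, Pan-Tompkins QRS
    detection, accelerometer fall detection, GPS speed estimation,
    cross-correlation synchronization of dual sensor streams, dynamic time
    warping over pose-contribution state sequences, behavioral-pattern
    statistics, and a database-driven danger-detection life cycle. A synthetic
    data module generates silhouette image sequences, accelerometer, ECG and
    GPS traces with ground truth so the whole pipeline is testable without
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    zoo,
    geosphere,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
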