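Package: trunkstrat
Title: Sensor-Based Risk Stratification of Nonspecific Low Back Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for stratifying nonspecific low back
    pain (NSLBP) patients into prognostic risk groups from wearable-sensor
    recordings. Takes trunk-mounted IMU streams (3-axis gyroscope and
    accelerometer at 20 Hz) recorded during a timed trunk flexion/extension
    task together with balance-board centre-of-pressure trajectories (40 Hz)
    and psychosocial questionnaire scores, segments movement cycles on the
    flexion/extension gyroscope axis, time-normalises each cycle to 101
    points and aggregates cycles by root mean square, builds four feature
    sets (full-signal, 16 summary statistics per channel, postural-sway
    measures, questionnaire scores), selects the cluster count by the
    Calinski-Harabasz index, and classifies risk groups with
    leave-one-participant-out cross-validated support vector machines and a
    multilayer perceptron, reporting accuracy, sensitivity, specificity,
    precision, F1 and the G-index over repeated balanced subsamples. A
    synthetic-cohort generator with configurable group effects makes the
    whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    ggplot2,
    generics,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
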