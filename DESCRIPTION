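Package: rehabglove
Title: Sensor-Glove Analytics for Post-Stroke Upper-Limb Rehabilitation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computation stack for a wearable sensor-glove rehabilitation
    system: data model and windowing for flex-sensor/IMU time series sampled
    at 21 Hz, seeded generators for labelled exercise streams and synthetic
    patient cohorts, a trainable 1-D convolutional window classifier with a
    sensor-ablation harness, star-based exercise feedback scoring and session
    scheduling, and a small-sample feasibility-trial analysis (paired,
    Student and Welch t-tests with assumption-check gating, Cohen's d,
    non-parametric sensitivity checks, and MCID/MDC annotation) computable
    from raw scores or printed summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
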