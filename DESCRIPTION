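Package: hmibench
Title: Benchmarking Forearm Human-Machine Interfaces for Proportional Finger-Force Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates multi-stream forearm interface recordings (surface
    electromyography envelopes, force-sensing-resistor pressure signatures,
    and ultrasound gray-level features) synchronized with six-channel
    finger-force ground truth, and benchmarks proportional force decoding
    across these modalities. Implements causal Butterworth preprocessing,
    closed-form ridge regression, the Random Fourier Feature approximation
    of the radial-basis-function kernel with bandwidth grid search,
    realistic-scenario training-set construction from extreme-force samples,
    repetition-wise cross-validated nRMSE accuracy evaluation, and a
    train-on-first-repetition stability analysis whose linear error slope
    quantifies signal drift (fatigue, sweat, baseline wander).
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
    tools
Suggests:
    kernlab,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
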