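Package: kneegait
Title: Spatiotemporal Gait Analysis from Knee-Worn Triaxial Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates five spatiotemporal gait characteristics (step time,
    stride time, step length, stride length, walking speed) from knee-worn
    triaxial accelerometer recordings through dynamic tilt correction,
    zero-phase Butterworth low-pass filtering, integration, detection of
    initial contacts as minima of a first-derivative-of-Gaussian continuous
    wavelet transform, and an extended inverted-pendulum step-length model.
    Also scores the Tinetti mobility test with fall-risk bands, validates
    estimates against reference motion-capture parameter tables (percentage
    error rates and Pearson correlation), and classifies Parkinson's disease
    versus healthy older adults from the estimated characteristics with
    k-nearest-neighbour, radial-basis support vector machine, Gaussian naive
    Bayes and pruned decision-tree classifiers under subject-wise stratified
    resampling. A ground-truth-annotated synthetic walking-signal generator
    makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    e1071,
    rpart,
    class,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
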