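Package: spontact
Title: Detection of Spontaneous and Evoked Activity in In Vivo Calcium Imaging Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting spontaneously active sensory neurons in
    in-vivo GCaMP6s fluorescence recordings. Provides trace preprocessing
    (background subtraction, dF/F0 normalisation, moving-average smoothing,
    linear-interpolation resampling), a standard-deviation threshold
    comparator, interval-based time-series forest classifiers (time series
    forest and random interval spectral ensemble) with a lidocaine-anchored
    training protocol, a baseline-referenced evoked-response detector,
    confusion-matrix evaluation utilities, and a forward simulator of
    dorsal root ganglion calcium recordings with known per-neuron ground
    truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
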