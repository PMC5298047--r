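Package: startlemod
Title: Model-Based Analysis of Startle Eyeblink Electromyography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Psychophysiological modelling of the startle eyeblink response
    (SEBR) recorded with orbicularis oculi electromyography. Implements the
    canonical gamma-shaped startle eyeblink response function, general linear
    convolution models and a dictionary-matching algorithm for trial-wise
    amplitude and latency estimation (models M1-M4 and single-trial variants),
    four published peak-scoring methods (B1, Br, G1, G2), within-subject
    normalization, AIC-based predictive-validity comparison across methods,
    Butterworth filter-band optimization, and a synthetic EMG generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
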