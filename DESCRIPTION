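Package: tstms
Title: Transdermal Spatiotemporal Multispectral Features for Remote
    Emotion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a remote photoplethysmography (rPPG) pipeline for
    classifying emotional states from multispectral (RGB, near-infrared and
    long-wave infrared) face videos. Recordings are spatially downsampled to
    a common 50 x 35 grid, the heart rate is estimated from a dominant
    frequency map of the green channel, per-pixel pulse peaks and troughs
    are located, and eight transdermal spatiotemporal multispectral (TSTMS)
    features grounded in Beer-Lambert skin optics are assembled into a
    61,251-value vector per trial. Trials are classified with class-weighted
    one-vs-one gradient boosting under leave-one-subject-out
    cross-validation, and feature importance is aggregated into spatial,
    temporal and wavelength views. A synthetic multispectral video simulator
    with known ground truth (heart rate, absorption coefficients,
    class-specific spatial modulation) exercises the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    EBImage,
    xgboost,
    pROC,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
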