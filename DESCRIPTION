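Package: pfreject
Title: Reject Options for Particle-Filter Pose Tracking in Depth Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Six degree-of-freedom particle-filter tracking of a rigid target
    in depth-image sequences, with machine-learned reject options that flag
    when the track has been lost. Provides a pinhole depth-scene simulator
    (smooth target motion, occlusion and sudden-displacement events,
    depth-dependent sensor noise), a log-domain particle filter with a
    per-pixel uniform/Gaussian/truncated-exponential mixture likelihood,
    windowed feature extraction over filter diagnostics, and three reject
    strategies: a Chow-style likelihood threshold, distance/angle regression,
    and a sparse ensemble of per-tolerance binary classifiers built by
    minimum set cover over shifted decision thresholds. Strategies are
    compared with walk-forward time-series cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    e1071,
    randomForest,
    kernlab,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
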