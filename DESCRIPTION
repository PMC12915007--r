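Package: oscidual
Title: Oscillatory Source Power, Multiclass Decoding and Gaze Metrics for
    Dual-Task M/EEG Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for factorial (workload by speech-valence)
    dual-task magnetoencephalography and eye-tracking experiments.
    Implements DICS beamformer source power with spatial pre-whitening and
    baseline-relative change, aperiodic (1/f) spectral parametrization and
    subtraction with individual band-peak detection, adjacency-based
    cluster permutation statistics for repeated-measures factorial designs,
    multiclass common spatial patterns decoding with regularized linear
    discriminant analysis and Haufe activation-pattern source localization,
    wavelet-based pupillometry (Index of Pupillary Activity), gaze
    dispersion, and a composite driving-performance score.  A synthetic
    cohort generator with planted condition effects supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
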