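Package: sleepwave
Title: Joint Detection of Sleep Spindles and K-Complexes by Sparse
    Oscillatory/Transient Decomposition of EEG
Version: 0.1.0
Authors@R:
    person("Sleepwave", "Developers", email = "sleepwave@example.org",
           role = c("aut", "cre"))
Description: Decomposes single-channel sleep EEG into an oscillatory and a
    transient morphological component with a tunable Q-factor wavelet
    transform (TQWT) and dual basis-pursuit denoising (morphological
    component analysis), detects sleep spindles from a complex
    frequency-B-spline wavelet time-frequency map of the oscillatory
    component and K-complexes from thresholded troughs of the band-pass
    filtered transient component, and trains detection thresholds from
    annotated segments with sensitivity-versus-FDR curves. Includes a
    synthetic sleep-EEG generator with ground-truth annotations, EDF and
    tab-separated annotation I/O, an RMS baseline spindle detector, and
    inter-annotator agreement metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
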