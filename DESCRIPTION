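Package: swallowseg
Title: Online Swallow Segmentation for High-Resolution Cervical
    Auscultation Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automatic segmentation of swallowing events in
    high-resolution cervical auscultation recordings (tri-axial
    accelerometry and swallowing sounds). Signals are scanned with a
    sliding window; each window is summarised by the magnitude of its
    short-time Fourier spectrogram (257 frequency bins by 5 frames,
    flattened to a 1285-length vector) and classified as swallow or
    non-swallow by a feed-forward probabilistic network trained with
    full-sweep stochastic gradient descent. Consecutive positive windows
    are assembled into segments whose borders are refined by thresholding
    the area under the spectral-estimate curve, and detections are scored
    against reference annotations under fixed-duration and
    fraction-of-reference overlap criteria. A seeded synthetic-signal
    simulator generates multi-channel recordings with exact ground-truth
    intervals so the full pipeline can be trained and evaluated at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
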