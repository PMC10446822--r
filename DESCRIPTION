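Package: bcialign
Title: Unsupervised Cross-Day Alignment of Neural Recordings for Stable
    Intracortical BCI Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for stabilizing a fixed intracortical brain-computer
    interface (iBCI) decoder against day-to-day turnover of recorded
    neurons.  Implements three unsupervised aligners that map 'day-k'
    multichannel firing rates back into 'day-0' coordinates: a
    cycle-consistent adversarial network (Cycle-GAN) operating on the
    full-dimensional rates, an adversarial domain adaptation network
    (ADAN) whose discriminator is an autoencoder scoring
    reconstruction-residual distributions, and Procrustes alignment of
    Factor-Analysis manifolds (PAF).  Also provides the lagged Wiener
    filter decoder frozen after day-0 calibration, the evaluation
    statistics used to score alignment (variance-weighted multivariate
    R-squared, maximum mean discrepancy with a Gaussian kernel family,
    principal angles between PCA subspaces with shuffle-surrogate and
    within-day bounds, peri-event time histograms), preprocessing for
    binned spike counts and EMG envelopes, and a synthetic
    nonstationary-recording simulator with known ground truth for
    benchmarking aligners end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
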