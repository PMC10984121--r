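Package: electromer
Title: Simulation, Characterization and Classification of Plant Electrome Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with electrophytograms, the extracellular
    voltage-variation time series that make up a plant's electrome. The
    package simulates stimulus-specific recordings (colored-noise baselines,
    action-potential- and variation-potential-like spike trains, salt-shock
    bursts and slow waves), computes a nine-statistic characterization ledger
    per series (mean voltage variation, skewness, kurtosis, power-law
    probability-density exponent, autocorrelation decay, power-spectral-density
    exponent, approximate entropy, Fourier spectrum and multiscale approximate
    entropy), reduces series to windowed min/mean/max interval triplets, and
    evaluates a roster of classifiers with learning curves, pooled confusion
    matrices and repeated-holdout Wilcoxon comparisons, plus paired
    before/after statistics with normality-based test routing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    dplyr,
    e1071,
    generics,
    graphics,
    ggplot2,
    nnet,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
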