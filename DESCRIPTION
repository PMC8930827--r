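Package: lfpgc
Title: Directed Spectral Connectivity Analysis for Multichannel LFP Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating directed effective
    connectivity in multichannel local field potential (LFP) recordings of a
    cortico-subthalamic network across disease states. Implements zero-phase
    preprocessing (band-pass, notch, anti-aliased resampling, segmentation,
    normalization), Welch power spectral density and magnitude-squared
    coherence, multivariate autoregressive (MVAR) modelling with BIC order
    selection and ordinary least squares estimation, time-domain and
    frequency-domain (Geweke) Granger causality over a five-node pairwise
    model in both bivariate and conditional modes, band-limited
    summarization, robust trial-level outlier filtering, and between-state
    inference via linear mixed-effects models and Mann-Whitney tests with
    Benjamini-Hochberg correction. Includes a synthetic study generator
    built on stable vector autoregressions with planted oscillatory
    couplings, 1/f background, line noise, and artifact trials, so every
    stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
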