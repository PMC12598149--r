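Package: calciburst
Title: Calcium Transient and Burst Analysis for Adrenal Slice Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trace-level analysis of GCaMP6f calcium-imaging recordings from
    adrenal zona glomerulosa slices: quality control of ROI fluorescence traces
    (neuropil subtraction, rolling-percentile detrending, moving-window SD-ratio
    exclusion), nonnegative sparse AR(1) deconvolution, dual-threshold transient
    detection with peak alignment and template validation, burst segmentation via
    the intersection of a Gaussian+exponential interpeak-interval mixture fitted
    by EM, and per-ROI / per-slice activity metrics (active-cell density, burst
    number and duration, fraction of time bursting, intraburst period). Also
    includes aldosterone-secretion fold-change normalization with four-parameter
    logistic dose-response fitting, and a synthetic-data generator that renders
    ground-truth bursting spike trains as noisy indicator fluorescence under
    named stimulation/osmolarity condition presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
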