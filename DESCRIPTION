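Package: vitalspec
Title: Spectral Feature Engineering and nu-SVC Mortality Prediction for ICU Vital-Sign Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes bedside-monitor vital-sign time series (SaO2, heart
    rate, respiration, ECG ST levels) from the first 24 hours of an ICU stay
    into Fourier, power-spectral-density, autocorrelation, and continuous
    wavelet representations; extracts relative-extrema, power-in-band,
    summary-statistic, and moving-window sudden-change features; and predicts
    ICU mortality with an L1-selected, class-weighted nu support vector
    classifier evaluated by stratified cross-validation. Includes a synthetic
    eICU-style cohort generator with planted class structure so the full
    pipeline can be exercised without access to credentialed clinical data,
    and a command-line entry point for config-driven runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    e1071,
    glmnet,
    pROC,
    yaml,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
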