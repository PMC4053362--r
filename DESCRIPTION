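Package: mlcp
Title: Conformal Region Prediction for Multi-Label Classification of
    Binary Clinical Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reliable multi-label classification via conformal prediction,
    motivated by syndrome differentiation of chronic fatigue in traditional
    Chinese medicine, where a patient described by binary symptoms carries a
    set of syndrome-factor labels. Multi-label cases are expanded into
    single-label examples (the PT5 problem transformation), nonconformity is
    scored with a random-forest proximity ratio (with K-nearest-neighbour
    and Bernoulli naive-Bayes variants), per-label conformal p-values are
    cut at a confidence threshold into region predictions, and online error
    rates are bounded by the significance level under exchangeability.
    Includes an ML-KNN baseline, the six standard multi-label evaluation
    metrics, a leave-one-out evaluation harness with calibration
    diagnostics, and a synthetic generator of chronic-fatigue-like
    multi-label symptom data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    ranger,
    rlang,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
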