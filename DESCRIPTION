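Package: cvcoupling
Title: Cardiovascular Coupling Analysis and Risk Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Beat-to-beat analysis of cardiovascular coupling from heart period
    (BBI), systolic (SBP) and diastolic (DBP) blood pressure series. Implements
    high-resolution joint symbolic dynamics with pattern-family grouping,
    segmented Poincare plot analysis, normalized short-time partial directed
    coherence from multivariate autoregressive models, the dual sequence method
    for spontaneous baroreflex sensitivity, and standard time- and
    frequency-domain heart rate and blood pressure variability indices.
    Includes adaptive artifact filtering, 2 Hz resampling, a seeded generator
    of coupled synthetic cohorts, nonparametric feature screening with
    correlation pruning, and support vector machine classification with
    Gaussian, Laplace and ANOVA kernels including a two-stage cascade for
    three-group risk stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    jsonlite
Config/testthat/edition: 3
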