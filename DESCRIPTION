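Package: crmpulse
Title: Explainable Compensatory Reserve Estimation from Arterial Pulse Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-based estimation of the compensatory reserve measurement
    (CRM), a 0-1 index of remaining physiological compensation against
    hypovolemia, from arterial pulse waveforms. Provides a synthetic
    lower-body-negative-pressure (LBNP) cohort simulator with ground-truth
    CRM labels, zero-phase FIR preprocessing and pulse landmark detection
    (foot, half-rise, systolic peak, post-systolic inflection), a 54-feature
    morphological catalogue, minimal-redundancy maximal-relevance (MRMR)
    feature ranking, six classical regression model families including
    bagged and boosted regression trees, and evaluation with both
    identity-line ("perfect") and conventional least-squares regression
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
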