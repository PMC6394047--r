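Package: reosig
Title: Rank-Based Gene-Pair Signatures for Qualitative Cancer Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery, application and evaluation of qualitative transcriptional
    signatures built from within-sample relative expression orderings (REOs) of
    gene pairs. Implements stable-pair mining at a configurable stability
    threshold, detection of reversal pairs between disease and non-disease
    classes, ranking by reversal degree (the geometric mean of class-wise mean
    absolute rank differences), top-k signature selection by training accuracy,
    majority-vote classification, and performance evaluation including the
    nonparametric Hanley-McNeil AUC with a normal-approximation confidence
    interval. Ships a synthetic-cohort generator with planted reversal pairs,
    batch-specific monotone measurement distortions and tumor-purity mixing, so
    the whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
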