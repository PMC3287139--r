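Package: mirsig
Title: miRNA Expression Signatures and Survival Risk Prediction for
    Chemoresistance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery and evaluation of microRNA expression signatures
    for cancer diagnosis and chemotherapy-resistance prediction from
    two-channel microarray log-ratio data. Provides lowess M-A
    normalization and replicate-probe collapsing, cancer-versus-normal
    differential signatures with a multi-classifier random-partition
    prediction protocol, per-miRNA proportional-hazards screening
    against time to progression, a supervised principal-component
    predictive index with percentile-based risk grouping,
    leave-one-out cross-validated Kaplan-Meier curves with permutation
    significance, paired pre/post-treatment resistance evaluation,
    delta-delta-Ct relative quantification of qPCR validations, and a
    synthetic-cohort generator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    survival,
    e1071,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
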