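Package: mlrldacp
Title: Sparse Linear Regression of Survival Time on lncRNA Expression for
    lncRNA-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the MlrLDAcp procedure: a multiple-linear-regression
    model that selects a sparse subset of long noncoding RNA (lncRNA)
    transcripts predictive of clinical survival time.  Candidate transcripts
    are screened for differential expression between normal and tumor
    samples, ranked by P value, and searched with an iterative bitwise
    variation operator (the Gamma operation, with a moving variation center
    and a decaying window width) combined with bidirectional stepwise-AIC
    model reduction.  The fitted coefficients score lncRNA-disease
    associations and predict patient survival; ROC/AUC and leave-one-out
    cross-validation evaluation harnesses and a synthetic cohort generator
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
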