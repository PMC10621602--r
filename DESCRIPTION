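Package: hierAUC
Title: Dependency-Adjusted Confidence Intervals for the AUC with
    Three-Level Hierarchical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the area under the ROC curve (AUC) from prediction
    scores observed on subunits nested within persons nested within families
    (e.g., eyes within patients within families).  Implements the extended
    Mann-Whitney estimator for three-level clustered data, a closed-form
    variance built from bivariate-normal concordance probabilities under a
    probit location-shift model, delta-method confidence intervals on the
    probit scale, repeated random tie-breaking with Rubin-rules pooling for
    tied scores, an independent-data (DeLong-type) comparator, and a Monte
    Carlo simulation harness for assessing bias, variance calibration and
    confidence-interval coverage under nested random-intercept models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
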