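Package: modstar
Title: Composite-Moderator Subgroup Identification for Two-Arm Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies subgroups with differential treatment benefit in
    two-arm randomized trials using the paired-difference composite
    moderator approach: per-variable moderator effect sizes from Spearman
    correlations over all cross-arm patient pairs with bootstrap
    confidence intervals, compilation of a composite moderator M* by
    lasso regression with k-fold cross-validation, cross-point
    subgrouping from the treatment-by-M* interaction, and evaluation of
    matched versus mismatched treatment assignment. Includes a synthetic
    trial generator emulating an 8-week comparison of psychotherapy
    (CBASP) versus escitalopram plus clinical management in persistent
    depressive disorder.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    e1071,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
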