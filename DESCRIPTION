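Package: mixbiome
Title: Weighted Quantile Sum Regression for Zero-Inflated Microbiome Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the joint association between a health variable and the
    whole microbial community as an environmental-mixture index. Implements
    weighted quantile sum (WQS) regression with random subsets and repeated
    holdouts for sample-by-taxon abundance tables: zero-anchored quantile
    scoring of relative abundances, simplex-constrained estimation of taxon
    weights over many random subsets, signal-function weighted averaging,
    stratified train/validation partitioning, and genus-level weight pooling.
    Also ships the companion outcome simulator (potency-adjusted logistic
    model with planted signal taxa), sensitivity/specificity evaluation of
    taxon identification, and standard comparators (Shannon diversity,
    Bray-Curtis/Aitchison distances, PERMANOVA, SIMPER, random-forest
    importance screening).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vegan,
    randomForest,
    biomformat,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
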