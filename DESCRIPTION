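Package: mscalefc
Title: Multi-Scale Functional Connectivity Features for Brain Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts multi-scale functional connectivity features from
    region-averaged fMRI BOLD time series: each region's series is binarized
    with a per-region dynamic (three-sigma) threshold, supra-threshold
    co-activations between ordered region pairs are counted over a set of lag
    intervals into a 3-order tensor, and the tensor is normalized to a
    discrete probability distribution whose entries are the features. Also
    provides the synchronous Pearson-correlation baseline, two-sample t-test
    feature selection, SVM/logistic/random-forest classifiers evaluated under
    leave-one-out cross-validation with accuracy, sensitivity, specificity and
    AUC, a synthetic BOLD-like cohort generator with group-dependent lagged
    couplings, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
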