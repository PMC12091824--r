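Package: ChiSquareEnsemble
Title: Chi-Square Weighted Ensembling of Multi-Class Classifier Predictions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistically weighted soft-voting for banks of multi-class
    classifiers. Each classifier is scored by a two-cell chi-square
    goodness-of-fit statistic comparing its observed correct/incorrect counts
    against the counts expected under a chance-agreement null derived from the
    true label distribution; weights proportional to the chi-square statistics
    then blend the classifiers' class-probability matrices. The weighting can
    be composed through a multi-layer ensemble topology (a DAG of ensemble
    nodes), and is accompanied by standard baselines (softmax averaging,
    majority voting, fixed weighted averaging), confusion-matrix metrics with
    support-weighted aggregation and one-vs-rest ROC-AUC, forward operators
    for channel, squeeze-excitation and soft attention on feature maps,
    Grad-CAM heatmap aggregation, and a synthetic prediction simulator with
    lesion-grouped train/validation/test splitting for leakage-free
    evaluation of dermoscopy-style imbalanced cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    png,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ChiSquareEnsemble-package.R'
    'attention.R'
    'baselines.R'
    'cli.R'
    'cwe.R'
    'gradcam.R'
    'methods.R'
    'metrics.R'
    'prediction-io.R'
    'synthetic.R'
    'topology.R'
    'utils.R'
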