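Package: transclock
Title: Transcriptomic Aging Clocks with Ensemble Feature-Importance Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds transcriptomic aging clocks from gene-expression matrices
    and derives consensus biomarker panels. Provides a multi-platform synthetic
    cohort generator with planted age-associated genes, quantile normalization
    with a reusable reference distribution, cluster-based cross-platform
    distribution transformation, five age-regression families (elastic net,
    linear-kernel support-vector regression, weighted k-nearest neighbours,
    random forest, and a deep feature-selection network with an elementwise
    input selection layer), evaluation metrics including epsilon-accuracy and
    multiclass pairwise AUC on binned ages, seven gene-importance rank sources
    (model coefficients, Gini importance, selection-layer weights, wrapper
    feature importance under permutation and directional fold-change
    perturbation, and two-group log2 fold change), and Borda-count rank
    aggregation into a final biomarker panel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
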