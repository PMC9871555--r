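Package: pmifusion
Title: Post-Mortem Interval Estimation from Lab-on-Chip Polypeptide Profiles
    by Multi-Organ Ensemble Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for classifying the post-mortem interval (PMI)
    of rats from microfluidic capillary electrophoresis (lab-on-chip) peptide
    peak tables. Peaks are matched across samples into a polypeptide fragment
    catalog by a 2 percent migration-time rule and a 5-of-6 replicate-support
    filter, per-organ classifiers are searched over a grid of four feature
    selectors and five learning algorithms, the best pipeline per organ is
    picked by a rank-sum score over eight validation metrics, and the four
    organ pipelines are fused by stacking, soft voting or soft-weighted
    voting with greedy backward ensemble pruning. A synthetic-data module
    emulates the rat study design (14 PMI classes, 6 rats per time point,
    4 organs, external cohort) so the whole pipeline runs without access to
    the original instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    e1071,
    xgboost,
    nnet,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
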