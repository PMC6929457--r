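Package: mmpcc
Title: Pseudo-Negative Sampling for Imbalanced Binary Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for handling class imbalance by pseudo-negative sampling:
    a greedy incremental selector (MMPCC) that identifies negative-labeled
    samples maximally correlated with the positive class and minimally
    redundant with already-selected samples, together with its single-criterion
    ablations (max-relevance MAXR, min-redundancy MINR), classical resampling
    baselines (SMOTE, random over- and under-sampling), a stratified
    cross-validation harness with sensitivity/specificity/accuracy/MCC
    reporting, a position-specific scoring matrix window featurizer, and a
    synthetic-data generator with planted pseudo-negatives for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    randomForest,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
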