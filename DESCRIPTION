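Package: megmvpa
Title: Time-Resolved Multivariate Decoding of Epoched MEG Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sensor-level multivariate pattern analysis (MVPA) for epoched
    multichannel electrophysiology data. Provides an epoch container with a
    trial table, a synthetic-epoch generator that emulates a statistical-
    learning visual-search design with planted spatial activity patterns,
    time-resolved linear classification (sliding-window features, class
    balancing, pseudotrial averaging, z-scoring, cross-validated AUC,
    univariate F feature selection, Haufe activation patterns), temporal
    generalization matrices and cross-epoch label-transfer analyses, and
    group-level inference by cluster-mass sign-flip permutation tests,
    Benjamini-Hochberg FDR, and JZS Bayes factors. A pipeline orchestrator
    runs simulate - decode - generalize - stats reproducibly from a single
    config and seed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
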