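Package: sacens
Title: Supervised Attribute Clustering Ensembles for Expression-Based
    Sample Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ensemble classification and biomarker ranking for
    high-dimensional expression matrices (bulk microarray or RNA-seq style
    data with tens to hundreds of samples and thousands of genes). Builds
    class-balanced bootstrap replicates of the training data, scores genes
    with seven filter statistics (Fisher score, Welch t, chi-square, mutual
    information, Pearson correlation, signal-to-noise ratio, Relief-F),
    refines each filter's top genes by a greedy supervised attribute
    clustering that merges positively or negatively co-expressed genes into
    signed cluster representatives, trains one base learner per reduced
    sub-dataset, predicts by majority vote, and ranks genes by how often
    they are selected across sub-datasets. Includes stratified k-fold,
    leave-one-out and repeated-split evaluation, ROC/AUC and confusion
    metrics, a seeded synthetic-data generator with planted differential
    expression, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    class,
    e1071,
    jsonlite,
    Rcpp,
    rpart,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
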