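Package: gannet
Title: Genetic-Algorithm-Optimized Neural Network Ensembles for SNP-Based
    Disease Risk Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control disease risk classification from candidate-gene SNP
    panels. Provides PLINK-text and TSV genotype input, SNP quality control,
    exact Hardy-Weinberg and allelic Fisher association tests with odds ratios
    and Woolf confidence intervals, EM-based linkage-disequilibrium r2 with
    greedy pruning, polygenic risk scores, six conventional machine-learning
    baselines, a small feed-forward neural network trained with Adam, and the
    core method: a genetic-algorithm search over fixed-size SNP subsets scored
    by neural-network fit, whose best subsets are combined into a six-member
    prediction-averaging ensemble. A synthetic genotype simulator with known
    causal structure supports end-to-end validation, and an iteration harness
    reports accuracy, weighted F1 and AUC with percentile confidence intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    e1071,
    randomForest,
    xgboost,
    rpart
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
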