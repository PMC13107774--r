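Package: lactoscreen
Title: Genome-Based Screening of Vaginal Lactobacillus Probiotic Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores vaginal Lactobacillus crispatus isolates for probiotic
    functional potential directly from genome assemblies. Builds concatenated
    multi-order (5-9) k-mer frequency features from FASTA assemblies, derives
    superior/suboptimal functional class labels from a weighted composite of
    in-vitro phenotypes (growth rate, acidification, lactic acid, hydrogen
    peroxide, pathogen antagonism), selects informative k-mers with a
    three-stage stability-enhanced procedure (low-variance and ANOVA
    filtering, subsample-averaged fusion of four importance metrics,
    correlation-clustering redundancy pruning), benchmarks eight classifier
    families by repeated-holdout AUC, and packages the best model as a
    self-contained bundle for prediction on new genomes. Includes a synthetic
    genome and phenotype simulator with planted discriminative k-mers for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    methods,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
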