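Package: crowdwisdom
Title: Crowd Wisdom as One-Dimensional Unsupervised Dimension Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates many individuals' answers to the same set of yes/no
    questions into a single consensus ranking by embedding the
    question-by-individual response matrix into one dimension. Provides PCA,
    factor analysis, Isomap, locally linear embedding (standard, Hessian and
    LTSA variants), spectral embedding and classical MDS aggregators alongside
    mean/median and the spectral meta-learner (SML) binary-vote baseline; a
    generative simulator of rater skill and question difficulty; orientation-
    aware ROC/PR evaluation; matched-FPR and proportion-of-differences
    comparisons between continuous and binary aggregates; and a stratified
    cross-validation harness benchmarking unsupervised consensus against
    supervised classifiers trained on labelled question subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    MASS,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
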