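Package: fmribucket
Title: Bucket-of-Models Consensus Classification of Task fMRI Activation Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates two clinical groups (chronic fatigue syndrome and
    Gulf War illness) from task-fMRI activation maps. Extracts per-subject
    suprathreshold voxel counts within the regions of a labelled brain atlas,
    screens the resulting feature table for multicollinearity, runs an
    iterative nine-classifier "bucket of models" build with recursive feature
    elimination and random-forest importance pruning, summarises the ensemble
    with agreement-threshold consensus curves (precision, sensitivity,
    specificity, false discovery rate), and assesses significance with a
    full-pipeline label-shuffle permutation test. Includes a synthetic cohort
    generator so every stage is testable without access to subject-level
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    rlang,
    RNifti,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
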