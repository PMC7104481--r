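Package: epitensor
Title: Multi-Scale Deep Tensor Factorization for Epigenomic Track Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Imputes epigenomic signal tracks across a biosample x assay x
    genomic-position tensor using a multi-scale deep tensor factorization
    model: latent factors for biosamples, assays, and three genomic
    resolutions feed a small feed-forward decoder trained by two-stage
    stochastic optimization. Includes protocols for extending a pre-trained
    model to new biosamples and assays (freeze-and-fit, fine-tuning, and
    retraining), an average-activity baseline, MSE- and precision-recall
    based evaluation with ambiguous-label handling, greedy cross-validation
    fold partitioning over experiment matrices, and a seeded synthetic
    compendium generator so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
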