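Package: methbatchsim
Title: Simulation-Based Evaluation of Batch-Effect Correction for
    Methylation Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates Illumina-style DNA methylation microarray data
    (27K/450K/EPIC beta-value matrices) from per-CpG mean/SD profiles,
    injects plate/chip/row batch effects and calibrated spike-in group
    differences, applies a from-scratch parametric empirical-Bayes batch
    correction (ComBat) with or without an outcome model matrix, and
    quantifies the resulting p-value inflation of moderated-t differential
    methylation statistics (mean p, genomic inflation factor lambda, FDR
    and Bonferroni false-positive counts) across sample layouts, batch
    factor structures, sample sizes and array platforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    limma,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
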