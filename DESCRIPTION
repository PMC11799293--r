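Package: methylight
Title: Interpretable DNA Methylation Age Clocks with Light-Up Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, benchmark and interpret DNA methylation (DNAm) age clocks
    from beta-value matrices. Provides reading, probe filtering and k-nearest
    neighbour imputation for methylation data; a simulator of cohorts with
    planted age-dependent CpG trajectories; a compact feed-forward neural
    network engine used to train methylome autoencoders, embedding-based age
    regressors, single-year cutoff classifiers and hybrid CpG-plus-embedding
    regressors; elastic-net CpG clocks; the light-up perturbation technique for
    ranking CpG contributions of a trained model and extracting signatures of
    aging; a two-setting cross-validated benchmarking harness with regression
    and classification metrics, Wilson score intervals and positive-prediction
    matrices; and over-representation analysis of signature-mapped genes
    against GMT gene-set collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    fgsea,
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
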