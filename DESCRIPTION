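Package: strivar
Title: Inter-Individual Variation in Striatal and Cortical snRNA-seq Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for characterizing inter-individual variation
    in multi-region, multi-donor single-nucleus RNA-seq studies of the human
    brain. Provides beta-binomial regression of cell-type abundance on age and
    sex with cluster-robust inference, cross-region sharing of donor-level
    propensities, conservative pairwise fold-difference summaries, pseudobulk
    differential expression with per-decade log2 fold-change effects and
    k-means effect-profile clustering, a moment-based transcriptome-wide
    impact estimator, elastic-net transcriptional aging clocks with
    GAM-corrected age residuals, cell-type-resolved cis-eQTL mapping with
    effect-pattern clustering and sharing statistics, genotype-based doublet
    accounting for pooled ("village") designs, and a synthetic cohort
    generator with a complete truth record for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    glmnet,
    mgcv,
    Matrix,
    MASS,
    methods,
    ggplot2,
    generics,
    jsonlite,
    readr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    mclust,
    withr
Config/testthat/edition: 3
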