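Package: rprsgxe
Title: Refined Polygenic Risk Scores and Gene-Environment Interaction
    Analysis
Version: 0.1.0
Authors@R:
    person("MAVAN", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to train, refine and transfer polygenic risk scores
    (PRS) between cohorts and to test whether the resulting score
    moderates the effect of cumulative early-life adversity on a
    behavioral outcome. Implements genotype/GWAS-summary input with
    allele alignment and quality control, LD pruning and clumping,
    principal components for population structure, a p-value threshold
    scan with per-SNP refinement (the "refined PRS"), cumulative
    adversity scoring with percentile dichotomization and hot-deck
    multiple imputation, delay-of-gratification task scoring, and
    moderated-regression diagnostics: simple slopes, Johnson-Neyman
    regions of significance, proportion-of-interaction and
    proportion-affected indices, non-parametric bootstrap and Rubin
    pooling. A synthetic two-cohort generator provides end-to-end
    testability without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
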