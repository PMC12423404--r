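Package: survgxe
Title: Two-Step Time-to-Event Gene-Environment Interaction Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exposure-stratified survival genome-wide association
    screening and Cox gene-environment interaction testing in biobank-scale
    cohorts. Implements a Cox proportional-hazards engine (Efron ties,
    Breslow baseline hazard, martingale residuals), per-variant score tests
    with saddlepoint-approximated tail probabilities for low event rates,
    genotype and sample quality control (Hardy-Weinberg exact test,
    relatedness pruning), LD-based clumping and merging of association
    signals into independent loci with nearest-gene annotation, a two-step
    interaction screen with locus-level Bonferroni correction and subgroup
    hazard-ratio profiling, and a synthetic biobank-cohort generator with
    planted genetic main and interaction effects so that every stage is
    testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    nnet,
    vcfR
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
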