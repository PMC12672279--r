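Package: droughtscreen
Title: Seedling-Stage Drought Tolerance Screening of Genotype Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for seedling-stage drought screening of crop
    genotype panels under graded osmotic (PEG 6000) stress.  Takes long-format
    genotype x treatment x replicate trait tables and produces descriptive
    statistics, balanced factorial ANOVA with Tukey pairwise treatment
    comparison, per-treatment Pearson correlation matrices, mean +/- SD
    efficiency scoring of genotypes, seven dry-weight based stress tolerance
    indices with a composite stress tolerance score, and principal component
    analysis of the index matrix.  Includes a calibrated synthetic-cohort
    generator for a completely randomized design and an algebraic auditor
    that back-derives control and stress dry weights from published index
    tables to verify their internal consistency.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
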