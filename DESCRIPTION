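Package: cptriomics
Title: Integrated Trio Genome and Transcriptome Diagnostics for Cerebral Palsy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated diagnostic pipeline for trio cohorts of children with
    cerebral palsy combining whole-genome genotypes and blood RNA-seq. Screens
    trios for damaging de novo variants (CADD, SIFT, PolyPhen-2 filters),
    classifies candidate variants into the five ACMG/AMP tiers from evidence
    codes with strength modifiers, detects per-proband aberrant expression
    (leave-one-out robust z) and aberrant splicing (intron clustering with a
    leave-one-out Dirichlet-multinomial likelihood-ratio test) using the
    remaining probands as controls, and flags pathway-level outliers from
    single-sample gene-set variation scores by Tukey fences. Ships a synthetic
    trio-cohort generator with a machine-readable truth registry so every stage
    is testable without access to patient data, plus exact 2x2 statistics
    (conditional-MLE odds ratio, exact two-sided p) shared across stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'stats-core.R'
    'acmg.R'
    'cohort-io.R'
    'cptriomics-package.R'
    'denovo.R'
    'expression-outliers.R'
    'gsva.R'
    'synthetic-cohort.R'
    'splicing-outliers.R'
    'pipeline.R'
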