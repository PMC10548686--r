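Package: pcgwas
Title: Principal-Component Biomarker Phenotypes for GWAS, Meta-Analysis and
    Mediation of Latent Alzheimer's Disease
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multivariate genome-wide association analysis of cerebrospinal
    fluid (CSF) biomarker profiles. Six CSF analytes (tau, pTau, Abeta42, NfL,
    YKL-40, neurogranin) are reduced to five varimax-rotated principal-component
    endophenotypes after rank-based inverse normal transformation and
    regularized iterative-PCA imputation of missing values, with the component
    count chosen by cell-wise cross-validation. Per-SNP association models
    (main, sex-stratified, SNP-by-sex interaction) are combined across studies
    by inverse-variance fixed-effect meta-analysis, aggregated into LD-aware
    gene-level tests, and genome-wide significant independent hits are carried
    into a mediation structural model in which SNPs act on a latent ordinal
    Alzheimer's disease outcome through the biomarker components. A synthetic
    two-study cohort generator with planted genetic, sex and diagnosis effects
    provides fully reproducible test data in place of restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    data.table,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
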