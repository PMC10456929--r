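Package: metadimorph
Title: Sexual Dimorphism Analysis for Knockout-Mouse Plasma Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for detecting sexual dimorphism in plasma
    metabolomics data from gene knockout (KO) mouse studies. Provides feature
    quality control (QC relative standard deviation and missingness filters),
    half-minimum imputation under a below-detection assumption, median batch
    normalization, sex-effect testing in wildtype mice with optional
    body-weight adjustment, nested-model two-way ANOVA for genotype and
    genotype-by-sex interaction effects with rule-based dimorphism
    classification, Kolmogorov-Smirnov chemical-cluster enrichment, per-sex
    Spearman metabolite-phenotype association, and a synthetic cohort
    generator with planted effect archetypes for power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
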