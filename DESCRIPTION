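Package: grsgdm
Title: Weighted Genetic Scores Across WHO 2013 Gestational Diabetes
    Diagnostic Subgroups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to relate weighted genetic scores for fasting plasma
    glucose and type 2 diabetes to the diagnostic subgroups of the WHO
    2013 criteria for gestational diabetes. Ships curated SNP weight
    panels (15 fasting-glucose and 38 type 2 diabetes variants with
    per-allele effect sizes and effect-allele frequencies), genotype
    input from dosage tables or VCF with effect-allele alignment,
    Hardy-Weinberg equilibrium screening with Bonferroni-based
    exclusion, weighted score construction with a strict complete-data
    rule, classification of oral glucose tolerance test results into
    fasting-only, 1-hour-only, 2-hour-only and combined hyperglycaemia
    subgroups, case-versus-control comparisons and glucose-on-score
    regressions with multiple-comparison correction, a power
    calculation for variance-explained predictors, and a seeded
    synthetic cohort generator with the assumed genotype-phenotype
    structure for end-to-end testing without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
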