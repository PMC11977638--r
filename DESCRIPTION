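Package: cfMRD
Title: Tumor-Informed ctDNA Detection from Whole-Genome Sequencing Read Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tumor-informed detection of circulating tumor DNA (ctDNA) in plasma
    whole-genome sequencing, driven by read counts at patient-specific somatic SNV
    sites. Builds per-patient SNV compendia with Gaussian-mixture filtering of
    FFPE-related low-VAF artifacts, scores plasma samples by their variant
    detection rate against a healthy-control noise model (Z score), estimates the
    plasma tumor fraction from variant read counts, fixes the classification
    threshold at a specificity constraint via ROC analysis, checks sample identity
    through SNP genotype concordance, and summarizes detection rates and tumor
    fractions across clinical groups. A synthetic cohort generator emulates the
    count-level structure of such a study so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    mclust,
    pROC,
    rlang,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
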