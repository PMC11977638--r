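#!/usr/bin/env Rscript
# Cohort-level report from the persisted run: per-group detection rates,
# TF medians/IQRs among positives, between-group rank-sum tests, and the
# comparison against the simulated deep-targeted assay on the CRC group.

suppressPackageStartupMessages({
  library(cfMRD)
  library(data.table)
})

results <- fread("results/run/results.tsv")
summ <- summarize_cohort(results)
print(summ)

fwrite(summ$group_summary, "results/run/report_group_summary.tsv", sep = "\t")
fwrite(summ$tf_tests, "results/run/report_tf_tests.tsv", sep = "\t")

crc <- results[group == "CRC" & !is.na(orthogonal_call)]
if (nrow(crc) >= 2) {
  agr <- compare_assays(crc)
  print(agr)
  jsonlite::write_json(unclass(agr), "results/run/report_assay_agreement.json",
                       auto_unbox = TRUE, digits = NA)
}
cat("report tables written under results/run/\n")
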