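#!/usr/bin/env Rscript
# Generate a demonstration synthetic cohort and persist its file interface:
# per-patient compendium VCFs, per-sample evidence TSVs, manifest and truth.
# A reduced mutation-load range keeps the on-disk demo small; the statistical
# structure (group TF medians, artifact rates, 20x depth) is the study default.

suppressPackageStartupMessages(library(cfMRD))

out <- "results/cohort"
cfg <- sim_config(n_patients_per_group = c(CRC = 8L, sAD = 4L, aAD = 4L),
                  n_controls = 6L,
                  compendium_size_range = c(500L, 1500L),
                  seed = 20260104L)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, out)

cat(sprintf("wrote %d patient compendia and %d control evidence tables to %s\n",
            length(cohort$patients), length(cohort$controls), out))
cat(sprintf("FFPE patients: %d of %d\n",
            sum(cohort$manifest$tissue == "FFPE", na.rm = TRUE),
            length(cohort$patients)))
print(cohort$truth[, c("sample_id", "group", "true_tf", "is_control")])
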