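#!/usr/bin/env Rscript
# Simulate the study cohort: 31 mice (SHAM 11 / HCD 10 / ANG 10), a
# 188-analyte p180-style panel measured in plasma and aorta, a shared
# latent aneurysmal-risk factor with a planted metabolite signature,
# dilution-like block-unique variation, lognormal noise and below-LOD
# censoring. Writes the two raw concentration tables that the rest of the
# workflow consumes.

suppressPackageStartupMessages(library(mocamet))

seed <- 1L
out_dir <- "results/cohort"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cohort <- generate_cohort(cohort_spec(seed = seed))

write_block(cohort$plasma, file.path(out_dir, "plasma.csv"))
write_block(cohort$aorta, file.path(out_dir, "aorta.csv"))
write.table(
  data.frame(sample_id = names(cohort$truth$risk),
             group = cohort$truth$groups,
             risk = cohort$truth$risk),
  file.path(out_dir, "ground_truth_risk.tsv"),
  sep = "\t", row.names = FALSE, quote = FALSE
)

message(sprintf("wrote %s: plasma %d x %d, aorta %d x %d (seed %d)",
                out_dir, nrow(cohort$plasma$values),
                ncol(cohort$plasma$values), nrow(cohort$aorta$values),
                ncol(cohort$aorta$values), seed))
message(sprintf("below-LOD cells: plasma %d, aorta %d",
                sum(!cohort$plasma$valid_mask),
                sum(!cohort$aorta$valid_mask)))
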