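#!/usr/bin/env Rscript
# Fit the two-block decomposition on the preprocessed cohort: mean-center
# and UV-scale each block, extract two joint components plus
# permutation-selected block-unique components, orient the first joint
# score so the aneurysm group is positive, and report variance explained.
# (The aorta table read here is already weight-normalized by 02.)

suppressPackageStartupMessages(library(mocamet))

in_dir <- "results/processed"
out_dir <- "results/moca"
set.seed(1L)  # permutation-based unique-component selection

plasma <- read_block(file.path(in_dir, "plasma.csv"), "plasma")
aorta <- read_block(file.path(in_dir, "aorta.csv"), "aorta")

scaled <- scale_blocks(list(plasma = plasma, aorta = aorta))
model <- fit_moca(scaled$matrices$plasma, scaled$matrices$aorta,
                  n_joint = 2L, n_unique = "auto",
                  block_names = c("plasma", "aorta"))
model <- orient_model(model, plasma$samples$group)
write_moca(model, out_dir)

scores <- data.frame(sample_id = plasma$samples$sample_id,
                     group = as.character(plasma$samples$group),
                     model$joint_scores)
write.table(scores, file.path(out_dir, "scores_with_groups.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

v <- variance_table(model)
message("variance explained (%):")
for (i in seq_len(nrow(v))) {
  message(sprintf("  %-8s %-9s %6.2f", v$block[i], v$component[i],
                  v$r2_pct[i]))
}
med <- tapply(model$joint_scores[, 1], as.character(plasma$samples$group),
              median)
message(sprintf("group medians on tj1: SHAM %.2f | HCD %.2f | ANG %.2f%s",
                med["SHAM"], med["HCD"], med["ANG"],
                if (med["SHAM"] < med["HCD"] && med["HCD"] < med["ANG"])
                  "  (ordered by aneurysmal risk)" else ""))
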