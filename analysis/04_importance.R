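#!/usr/bin/env Rscript
# Variable importance on the first joint component: Kendall tau-b between
# each metabolite and the consensus risk score, Benjamini-Hochberg
# selection at FDR 5% per block, and 3D-volcano coordinates
# (loading, tau, -log10 p). Refits the decomposition from the processed
# tables (deterministic) rather than deserializing model internals.

suppressPackageStartupMessages(library(mocamet))

in_dir <- "results/processed"
out_dir <- "results/importance"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
set.seed(1L)

plasma <- read_block(file.path(in_dir, "plasma.csv"), "plasma")
aorta <- read_block(file.path(in_dir, "aorta.csv"), "aorta")
scaled <- scale_blocks(list(plasma = plasma, aorta = aorta))
model <- orient_model(
  fit_moca(scaled$matrices$plasma, scaled$matrices$aorta,
           n_joint = 2L, n_unique = "auto",
           block_names = c("plasma", "aorta")),
  plasma$samples$group
)

for (b in c("plasma", "aorta")) {
  blk <- if (b == "plasma") plasma else aorta
  imp <- importance_table(scaled$matrices[[b]], model, b, q = 0.05,
                          classes = blk$metabolites)
  write.table(imp, file.path(out_dir, paste0("importance_", b, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(volcano_coordinates(imp),
              file.path(out_dir, paste0("volcano_", b, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  bh <- attr(imp, "bh")
  message(sprintf(
    "%s: %d/%d significant at FDR 5%% (alpha threshold %.4g)",
    b, bh$n_significant, nrow(imp), bh$alpha_threshold
  ))
  top <- imp[imp$significant, ]
  top <- head(top[order(-abs(top$tau)), ], 8L)
  for (i in seq_len(nrow(top))) {
    message(sprintf("  %-16s tau %+.3f  loading %+.3f  p %.2e",
                    top$metabolite[i], top$tau[i], top$loading[i],
                    top$p_value[i]))
  }
}
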