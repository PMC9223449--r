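#!/usr/bin/env Rscript
# Preprocess both blocks: dynamic-range filter (retain metabolites with
# strictly more than 70% of values quantified), normalize aorta
# concentrations by wet weight (uM -> uM/mg), and impute remaining
# below-LOD cells with half the metabolite's minimum quantified value.
# Writes analysis-ready tables plus the dropped-metabolite reports.

suppressPackageStartupMessages(library(mocamet))

in_dir <- "results/cohort"
out_dir <- "results/processed"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

plasma <- read_block(file.path(in_dir, "plasma.csv"), "plasma")
aorta <- read_block(file.path(in_dir, "aorta.csv"), "aorta")

for (tissue in c("plasma", "aorta")) {
  b <- if (tissue == "plasma") plasma else aorta
  f <- filter_dynamic_range(b, min_fraction = 0.70)
  dropped <- attr(f, "dropped")
  write.table(dropped, file.path(out_dir, paste0("dropped_", tissue, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  if (tissue == "aorta") f <- normalize_by_weight(f)
  f <- impute_below_lod(f, "half_min")
  write_block(f, file.path(out_dir, paste0(tissue, ".csv")))
  message(sprintf(
    "%s: retained %d/%d metabolites (dropped %d), imputed %d cells%s",
    tissue, ncol(f$values), ncol(b$values), nrow(dropped),
    attr(f, "n_imputed"),
    if (tissue == "aorta") ", normalized to uM/mg" else ""
  ))
}
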