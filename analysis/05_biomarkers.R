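#!/usr/bin/env Rscript
# Class sums, ratio statistics and biomarker evaluation: pairwise
# Mann-Whitney-Wilcoxon tests on the candidate ratios across groups (BH
# over the ratio x pair family), then ROC AUC with DeLong 95% CI per
# contrast (ANG vs no-ANG pooled, HCD vs ANG, SHAM vs HCD) against the
# 0.80 performance cutoff.

suppressPackageStartupMessages(library(mocamet))

in_dir <- "results/processed"
out_dir <- "results/biomarkers"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

blocks <- list(
  plasma = read_block(file.path(in_dir, "plasma.csv"), "plasma"),
  aorta = read_block(file.path(in_dir, "aorta.csv"), "aorta")
)
specs <- default_biomarker_specs()

# group-wise medians and pairwise tests per ratio
med_rows <- list(); mw_rows <- list()
for (tissue in names(specs)) {
  blk <- blocks[[tissue]]
  grp <- as.character(blk$samples$group)
  for (sp in specs[[tissue]]) {
    stat <- ratio_statistic(blk, sp)
    med <- tapply(stat, factor(grp, c("SHAM", "HCD", "ANG")), median)
    med_rows[[length(med_rows) + 1L]] <- data.frame(
      tissue = tissue, spec = sp$name,
      median_SHAM = med["SHAM"], median_HCD = med["HCD"],
      median_ANG = med["ANG"], row.names = NULL
    )
    mw <- mannwhitney_pairwise(stat, grp)
    mw_rows[[length(mw_rows) + 1L]] <-
      cbind(tissue = tissue, spec = sp$name, mw)
  }
}
medians <- do.call(rbind, med_rows)
mw <- do.call(rbind, mw_rows)
mw$p_adj <- p.adjust(mw$p_value, "BH")  # BH over the full ratio x pair family
write.table(medians, file.path(out_dir, "ratio_medians.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(mw, file.path(out_dir, "pairwise_tests.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

rocs <- do.call(rbind, lapply(names(specs), function(tissue) {
  cbind(tissue = tissue,
        evaluate_biomarkers(blocks[[tissue]], specs[[tissue]]))
}))
write.table(rocs, file.path(out_dir, "roc_report.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

message("group medians per ratio:")
for (i in seq_len(nrow(medians))) {
  message(sprintf("  %-7s %-11s SHAM %.3f | HCD %.3f | ANG %.3f",
                  medians$tissue[i], medians$spec[i],
                  medians$median_SHAM[i], medians$median_HCD[i],
                  medians$median_ANG[i]))
}
message("ROC (DeLong 95% CI), cutoff 0.80:")
for (i in seq_len(nrow(rocs))) {
  message(sprintf("  %-7s %-11s %-12s AUC %.3f [%.3f, %.3f]%s", rocs$tissue[i],
                  rocs$spec[i], rocs$contrast[i], rocs$auc[i],
                  rocs$ci_low[i], rocs$ci_high[i],
                  if (rocs$good_classifier[i]) {
                    if (rocs$lci_below_cutoff[i])
                      "  good (LCI includes cutoff)" else "  good"
                  } else ""))
}
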