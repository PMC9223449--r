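test_that("importance table requires an oriented model and flags planted signal", {
  set.seed(83)
  cohort <- generate_cohort(cohort_spec(seed = 83L))
  pl <- impute_below_lod(filter_dynamic_range(cohort$plasma))
  ao <- impute_below_lod(filter_dynamic_range(
    normalize_by_weight(cohort$aorta)))
  sc <- scale_blocks(list(plasma = pl, aorta = ao))
  model <- fit_moca(sc$matrices$plasma, sc$matrices$aorta,
                    n_joint = 2L, n_unique = c(1L, 1L),
                    block_names = c("plasma", "aorta"))
  expect_error(importance_table(sc$matrices$plasma, model, "plasma"),
               "orient")
  model <- orient_model(model, pl$samples$group)
  imp <- importance_table(sc$matrices$plasma, model, "plasma",
                          classes = pl$metabolites)
  expect_equal(nrow(imp), ncol(sc$matrices$plasma))
  expect_equal(imp$neg_log10_p, -log10(imp$p_value))
  # BH consistency: every significant p at or below the alpha threshold
  bh <- attr(imp, "bh")
  expect_true(all(imp$p_value[imp$significant] <= bh$alpha_threshold))
  expect_equal(sum(imp$significant), bh$n_significant)
  # planted BCAA-up / Gly-down signature recovered with correct tau signs
  expect_gt(imp$tau[imp$metabolite == "Leu"], 0)
  expect_lt(imp$tau[imp$metabolite == "Gly"], 0)
  expect_lt(imp$loading[imp$metabolite == "Gly"], 0)

  # a metabolite identical to the score ranks at tau = 1 and is significant
  x2 <- cbind(sc$matrices$plasma[, 1:10], tj = model$joint_scores[, 1])
  colnames(x2) <- NULL
  model2 <- model
  model2$joint_loadings$plasma <- rbind(
    model$joint_loadings$plasma[1:10, , drop = FALSE],
    tj = c(1, 0)
  )
  imp2 <- importance_table(x2, model2, "plasma")
  expect_equal(imp2$tau[11], 1)
  expect_true(imp2$significant[11])
})

test_that("orientation flip negates loadings and tau but not p-values", {
  set.seed(89)
  cohort <- generate_cohort(cohort_spec(seed = 89L))
  pl <- impute_below_lod(filter_dynamic_range(cohort$plasma))
  ao <- impute_below_lod(filter_dynamic_range(
    normalize_by_weight(cohort$aorta)))
  sc <- scale_blocks(list(plasma = pl, aorta = ao))
  model <- orient_model(
    fit_moca(sc$matrices$plasma, sc$matrices$aorta, n_joint = 1L,
             n_unique = c(0L, 0L), block_names = c("plasma", "aorta")),
    pl$samples$group
  )
  anti <- model
  anti$joint_scores <- -anti$joint_scores
  anti$joint_loadings <- lapply(anti$joint_loadings, function(l) -l)
  a <- importance_table(sc$matrices$plasma, model, "plasma")
  b <- importance_table(sc$matrices$plasma, anti, "plasma")
  expect_equal(b$tau, -a$tau)
  expect_equal(b$loading, -a$loading)
  expect_equal(b$p_value, a$p_value)
  expect_equal(b$significant, a$significant)
})

test_that("volcano coordinates carry the class color key and round-trip", {
  rec <- data.frame(
    metabolite = c("PC aa C36:2", "Gly", "H1"),
    class = c("phosphatidylcholine", "aminoacid", "hexose"),
    loading = c(0.5, -0.3, 0.1),
    tau = c(0.6, -0.4, 0.1),
    p_value = c(0.01, 1, 0.2),
    significant = c(TRUE, FALSE, TRUE)
  )
  v <- volcano_coordinates(rec)
  expect_equal(v$z_neg_log10_p, c(2, 0, -log10(0.2)))
  expect_equal(v$color, c("red", "grey", "orange"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(v, path, sep = "\t", row.names = FALSE, quote = FALSE)
  v2 <- read.delim(path, check.names = FALSE)
  expect_equal(v2$z_neg_log10_p, v$z_neg_log10_p, tolerance = 1e-12)
  expect_equal(v2$x_loading, v$x_loading, tolerance = 1e-12)
})
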