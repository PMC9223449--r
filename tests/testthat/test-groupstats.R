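test_that("Mann-Whitney pairwise: symmetry, exact enumeration, permutation check", {
  # identical distributions in both groups -> U = n1 n2 / 2, p = 1
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("SHAM", "HCD"), each = 3)
  r <- mannwhitney_pairwise(v, g)
  expect_equal(r$U, 4.5)
  expect_equal(r$p_value, 1)

  # complete separation, n1 = n2 = 3: exact two-sided p = 2 / C(6,3) = 0.1
  r2 <- mannwhitney_pairwise(c(1, 2, 3, 10, 11, 12), g)
  expect_equal(r2$p_value, 0.1)
  expect_equal(r2$U, 0)

  expect_error(mannwhitney_pairwise(1:3, c("SHAM", "SHAM", "HCD")),
               ">= 2 samples")

  # normal-approximation p matches a permutation estimate
  set.seed(59)
  x <- rnorm(10); y <- rnorm(10, 0.8)
  vals <- c(x, y); grp <- rep(c("SHAM", "ANG"), each = 10)
  p_obs <- mannwhitney_pairwise(vals, grp)$p_value
  u_obs <- mannwhitney_pairwise(vals, grp)$U
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  dev <- abs(u_stat(x, y) - 50)
  perm <- replicate(20000, {
    s <- sample(20)
    abs(u_stat(vals[s[1:10]], vals[s[11:20]]) - 50) >= dev - 1e-9
  })
  # tolerance covers Monte-Carlo error plus the (no-continuity-correction)
  # normal-approximation error at n = 10 per group
  expect_lt(abs(p_obs - mean(perm)), 0.05)
})

test_that("class sums follow the panel taxonomy rules", {
  vals <- matrix(c(100, 50, 150, 5, 1, 2, 3), nrow = 1)
  b <- toy_block(vals, groups = "SHAM",
                 met_names = c("Leu", "Ile", "Val", "C2", "C12", "C14",
                               "C18:1"))
  expect_equal(unname(class_sum(b, "BCAA")), 300)
  # LCAC: strictly more than 12 carbons -> C14 and C18:1 only
  expect_equal(unname(class_sum(b, "LCAC")), 2 + 3)
  expect_equal(unname(class_sum(b, "total_carnitine")), 5 + 1 + 2 + 3)
  expect_error(class_sum(b, "SM"), "matches no metabolite")
  # brute-force masked sum on a random panel
  set.seed(61)
  panel <- default_panel()
  big <- toy_block(matrix(rexp(5 * 188), 5, 188), met_names = panel$name)
  sel <- panel$class == "phosphatidylcholine"
  expect_equal(class_sum(big, "PC"),
               apply(big$values, 1, function(r) sum(r[sel])))
})

test_that("ratio statistics: partition, units, per-sample definition", {
  vals <- matrix(c(4, 1, 2, 3, 300, 150), nrow = 1)
  b <- toy_block(vals, groups = "SHAM",
                 met_names = c("lysoPC a C18:0", "lysoPC a C16:0",
                               "lysoPC a C18:1", "lysoPC a C20:4",
                               "Leu", "Gly"))
  us <- ratio_spec("U/S", "lysoPC_unsat", "lysoPC_sat")
  expect_equal(unname(ratio_statistic(b, us)), (2 + 3) / (4 + 1))
  bg <- ratio_spec("BCAA/Gly", "Leu", "Gly")
  expect_equal(unname(ratio_statistic(b, bg)), 2.0)

  # unit-free: rescaling the whole block leaves ratios unchanged
  set.seed(67)
  panel <- default_panel()
  big <- toy_block(matrix(rexp(8 * 188), 8, 188), met_names = panel$name)
  big2 <- big; big2$values <- big$values * 7.3
  spec <- ratio_spec("LysoPC/PC", "lysoPC", "PC")
  expect_equal(ratio_statistic(big2, spec), ratio_statistic(big, spec))

  # group medians of ratios are medians of per-sample ratios
  r <- ratio_statistic(big, spec)
  grp <- as.character(big$samples$group)
  med_oracle <- vapply(split(seq_len(8), grp), function(ix) {
    median(rowSums(big$values[ix, panel$class == "lysophosphatidylcholine",
                              drop = FALSE]) /
             rowSums(big$values[ix, panel$class == "phosphatidylcholine",
                                drop = FALSE]))
  }, numeric(1))
  expect_equal(vapply(split(r, grp), median, numeric(1)), med_oracle)
})

test_that("DeLong AUC: pair counting, flips, and agreement with pROC", {
  r <- roc_auc_delong(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$ci_low, 1)  # zero variance, clipped

  r2 <- roc_auc_delong(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r2$auc, 3 / 4)

  set.seed(71)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4) == 1
  r3 <- roc_auc_delong(scores, labels)
  auc_b <- brute_auc(scores, labels)
  expect_equal(if (r3$flipped) 1 - auc_b else auc_b, r3$auc,
               tolerance = 1e-12)
  # U / (n_pos * n_neg) identity via wilcox.test
  U <- unname(wilcox.test(scores[labels], scores[!labels],
                          exact = FALSE)$statistic)
  expect_equal(U / (sum(labels) * sum(!labels)),
               if (r3$flipped) 1 - r3$auc else r3$auc, tolerance = 1e-12)

  skip_if_not_installed("pROC")
  ci <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE,
                               direction = if (r3$flipped) ">" else "<"),
                     method = "delong")
  expect_equal(r3$auc, as.numeric(ci[2]), tolerance = 1e-12)
  expect_equal(r3$ci_low, max(0, as.numeric(ci[1])), tolerance = 1e-10)
  expect_equal(r3$ci_high, min(1, as.numeric(ci[3])), tolerance = 1e-10)

  # label swap mirrors the interval around the flipped AUC
  r4 <- roc_auc_delong(scores, !labels)
  expect_equal(r4$auc, r3$auc)  # orientation flip keeps reported AUC >= 0.5
  expect_error(roc_auc_delong(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(73)
  scores <- rexp(30)
  labels <- rbinom(30, 1, 0.5) == 1
  r0 <- roc_auc_delong(scores, labels)
  r1 <- roc_auc_delong(log(scores), labels)
  r2 <- roc_auc_delong(rank(scores), labels)
  expect_equal(r1$auc, r0$auc)
  expect_equal(r2$auc, r0$auc)
  # single-feature logistic regression is a monotone transform of the score
  lp <- predict(glm(labels ~ scores, family = binomial), type = "link")
  expect_equal(roc_auc_delong(lp, labels)$auc, r0$auc)
})

test_that("biomarker evaluation reports per-spec, per-contrast ROC rows", {
  set.seed(79)
  cohort <- generate_cohort(cohort_spec(seed = 79L))
  pl <- impute_below_lod(filter_dynamic_range(cohort$plasma))
  tab <- evaluate_biomarkers(pl, default_biomarker_specs()$plasma)
  expect_equal(nrow(tab), 9L)
  expect_true(all(tab$ci_low <= tab$auc & tab$auc <= tab$ci_high))
  expect_true(all(tab$auc >= 0.5))
  # a ratio equal to a group indicator plus tiny noise -> AUC ~ 1
  ind <- toy_block(
    cbind(1000 * (pl$samples$group == "ANG") + abs(rnorm(31, 1, 0.01)),
          rep(1, 31)),
    groups = as.character(pl$samples$group),
    met_names = c("Leu", "Gly")
  )
  r <- evaluate_biomarkers(ind, list(ratio_spec("ind", "Leu", "Gly")))
  expect_gt(r$auc[r$contrast == "ANG_vs_rest"], 0.99)
  expect_true(r$good_classifier[r$contrast == "ANG_vs_rest"])
})
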