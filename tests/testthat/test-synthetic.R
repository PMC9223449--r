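test_that("generator is deterministic and honors the design layout", {
  spec <- cohort_spec(seed = 101L)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$plasma$values, b$plasma$values)
  expect_identical(a$aorta$values, b$aorta$values)
  expect_identical(a$truth$risk, b$truth$risk)

  expect_equal(as.integer(table(a$plasma$samples$group)[
    c("SHAM", "HCD", "ANG")]), c(11L, 10L, 10L))
  expect_equal(ncol(a$plasma$values), 188L)
  expect_true(all(a$aorta$samples$aorta_weight_mg > 0))
  # planted risk factor ordered by construction
  med <- tapply(a$truth$risk, a$truth$groups, median)
  expect_true(med["SHAM"] < med["HCD"] && med["HCD"] < med["ANG"])
  # censoring marks round(q * m) lowest values per metabolite
  expect_equal(colSums(!a$plasma$valid_mask),
               rep(round(0.02 * 31), 188L), ignore_attr = TRUE)
  j <- 5L
  expect_equal(which(!a$plasma$valid_mask[, j]),
               which.min(a$plasma$values[, j]), ignore_attr = TRUE)
})

test_that("weight normalization exactly recovers the planted aorta matrix", {
  cohort <- generate_cohort(cohort_spec(seed = 103L))
  norm <- normalize_by_weight(cohort$aorta)
  # planted per-mg concentrations are lognormal around class baselines:
  # check the hexose column sits near its baseline after normalization
  h1 <- norm$values[, "H1"]
  expect_true(all(h1 > 500 & h1 < 50000))
  # and raw values are per-mg values times the weight
  expect_equal(cohort$aorta$values,
               norm$values * cohort$aorta$samples$aorta_weight_mg)
})

test_that("planted plasma signature is self-consistent (BCAA vs risk)", {
  hits <- vapply(1:40, function(s) {
    cohort <- generate_cohort(cohort_spec(seed = 1000L + s))
    pl <- impute_below_lod(filter_dynamic_range(cohort$plasma))
    bcaa <- class_sum(pl, "BCAA")
    kendall_tau(bcaa, cohort$truth$risk)$tau > 0
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("null cohort removes the joint structure", {
  spec <- cohort_spec(seed = 107L)
  nc <- null_cohort(spec)
  expect_identical(nc$truth$spec$fracs[["joint"]], 0)
  # no metabolite should track the (now unused) risk factor beyond chance
  pl <- impute_below_lod(filter_dynamic_range(nc$plasma))
  taus <- apply(pl$values[, 1:50], 2, function(col) {
    kendall_tau(col, nc$truth$risk)$tau
  })
  expect_lt(mean(abs(taus)), 0.2)
})

test_that("heavy censoring drives metabolites below the retention rule", {
  spec <- cohort_spec(seed = 109L, lod_quantile = 0.35)
  cohort <- generate_cohort(spec)
  f <- filter_dynamic_range(cohort$plasma)
  expect_equal(ncol(f$values), 0L)  # 20/31 = 64.5% valid everywhere
  expect_equal(nrow(attr(f, "dropped")), 188L)
})

test_that("recovery degrades monotonically as noise rises", {
  # seed-averaged, paired seeds across noise levels; per-column recovery
  # metrics (signature tau strength, planted-ratio AUC) fall with noise
  metrics_at <- function(noise_frac, n_seeds = 12L) {
    out <- vapply(100L + seq_len(n_seeds), function(s) {
      fr <- c(joint = 0.4 * (1 - noise_frac) / 0.6,
              unique = 0.2 * (1 - noise_frac) / 0.6,
              noise = noise_frac)
      fr <- fr / sum(fr)
      cohort <- generate_cohort(cohort_spec(seed = s, fracs = fr))
      pl <- impute_below_lod(filter_dynamic_range(cohort$plasma))
      auc <- roc_auc_delong(
        class_sum(pl, "BCAA") / class_sum(pl, "Gly"),
        pl$samples$group == "ANG"
      )$auc
      named <- c("Leu", "Ile", "Val", "Gly", "Gln", "Taurine", "C0")
      taus <- vapply(named, function(nm) {
        kendall_tau(pl$values[, nm], cohort$truth$risk)$tau
      }, numeric(1))
      c(auc = auc, tau = mean(abs(taus)))
    }, numeric(2))
    rowMeans(out)
  }
  r <- vapply(c(0.3, 0.5, 0.7), metrics_at, numeric(2))
  expect_true(all(diff(r["auc", ]) <= 0))
  expect_true(all(diff(r["tau", ]) <= 0))
})
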