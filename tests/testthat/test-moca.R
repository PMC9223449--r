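test_that("scaling yields exact zero means and unit variances", {
  set.seed(21)
  x1 <- matrix(rnorm(31 * 20, 5, 3), 31, 20)
  x2 <- matrix(rexp(31 * 12), 31, 12)
  sc <- scale_blocks(list(a = x1, b = x2))
  for (mat in sc$matrices) {
    expect_lt(max(abs(colMeans(mat))), 1e-10)
    expect_lt(max(abs(apply(mat, 2, var) - 1)), 1e-10)
  }
  # closed form: column (1,2,3) -> (-1, 0, 1) / sd
  sc3 <- scale_blocks(list(matrix(1:3, 3, 1), matrix(c(2, 9, 4), 3, 1)))
  expect_equal(drop(sc3$matrices[[1]]), c(-1, 0, 1) / sd(1:3))
  # idempotence on already-scaled data
  sc2 <- scale_blocks(sc$matrices)
  expect_lt(max(abs(sc2$matrices[[1]] - sc$matrices[[1]])), 1e-10)
  # constant columns are refused by name
  x1c <- x1; x1c[, 3] <- 7; colnames(x1c) <- paste0("m", 1:20)
  expect_error(scale_blocks(list(x1c, x2)), "m3")
})

test_that("noiseless rank-1 shared structure is recovered exactly", {
  set.seed(5)
  t <- rnorm(12); p <- rnorm(6); q <- rnorm(4)
  model <- fit_moca(tcrossprod(t, p), tcrossprod(t, q),
                    n_joint = 1L, n_unique = c(0L, 0L))
  expect_gt(abs(cor(model$joint_scores[, 1], t)), 1 - 1e-8)
  for (b in model$block_names) {
    expect_equal(model$r2[[b]]$joint, 1, tolerance = 1e-10)
    expect_equal(model$r2[[b]]$residual, 0, tolerance = 1e-10)
  }
  vt <- variance_table(model)
  expect_equal(vt$r2_pct[vt$component == "joint_1"], c(100, 100),
               tolerance = 1e-8)
})

test_that("joint + unique + residual reconstructs the input; scores orthogonal", {
  set.seed(8)
  m <- 31
  x1 <- scale(matrix(rnorm(m * 25), m, 25))
  x2 <- scale(matrix(rnorm(m * 18), m, 18))
  model <- fit_moca(x1, x2, n_joint = 2L, n_unique = c(2L, 3L),
                    block_names = c("pl", "ao"))
  for (b in c("pl", "ao")) {
    x <- if (b == "pl") x1 else x2
    rec <- reconstruct_block(model, b, x)
    expect_lt(max(abs(rec$joint + rec$unique + rec$residual - x)), 1e-8)
    r2 <- model$r2[[b]]
    expect_equal(sum(r2$joint) + sum(r2$unique) + r2$residual, 1,
                 tolerance = 1e-8)
    # unique scores orthogonal to every joint score
    cross <- crossprod(model$joint_scores, model$unique_scores[[b]])
    expect_lt(max(abs(cross)), 1e-8)
  }
  expect_lt(abs(crossprod(model$joint_scores)[1, 2]), 1e-8)
})

test_that("first joint direction agrees with brute-force SVD of the cross-product", {
  set.seed(13)
  for (rep in 1:5) {
    m <- sample(6:10, 1)
    x1 <- scale(matrix(rnorm(m * 4), m, 4))
    x2 <- scale(matrix(rnorm(m * 5), m, 5))
    model <- fit_moca(x1, x2, n_joint = 1L, n_unique = c(0L, 0L))
    s <- svd(crossprod(x1, x2))
    t1 <- x1 %*% s$u[, 1]; t2 <- x2 %*% s$v[, 1]
    if (sum(t1 * t2) < 0) t2 <- -t2
    consensus <- svd(cbind(t1, t2))$u[, 1]
    expect_gt(abs(cor(model$joint_scores[, 1], consensus)), 0.999)
  }
})

test_that("column permutation permutes loadings and leaves scores unchanged", {
  set.seed(17)
  x1 <- scale(matrix(rnorm(31 * 15), 31, 15))
  x2 <- scale(matrix(rnorm(31 * 10), 31, 10))
  perm <- sample(15)
  m0 <- fit_moca(x1, x2, n_joint = 2L, n_unique = c(1L, 1L))
  m1 <- fit_moca(x1[, perm], x2, n_joint = 2L, n_unique = c(1L, 1L))
  expect_equal(m1$joint_scores, m0$joint_scores, tolerance = 1e-8)
  expect_equal(unname(m1$joint_loadings[[1]]),
               unname(m0$joint_loadings[[1]][perm, ]), tolerance = 1e-8)
  expect_equal(unname(m1$joint_loadings[[2]]),
               unname(m0$joint_loadings[[2]]), tolerance = 1e-8)
})

test_that("orientation pins ANG positive, is idempotent, and flips loadings", {
  set.seed(23)
  groups <- rep(c("SHAM", "HCD", "ANG"), c(11, 10, 10))
  risk <- (groups == "ANG") - (groups == "SHAM") + rnorm(31, 0, 0.2)
  x1 <- scale(outer(risk, rnorm(20)) + matrix(rnorm(31 * 20, 0, 0.5), 31, 20))
  x2 <- scale(outer(risk, rnorm(15)) + matrix(rnorm(31 * 15, 0, 0.5), 31, 15))
  model <- fit_moca(x1, x2, n_joint = 1L, n_unique = c(0L, 0L))
  # force the wrong sign, then orient
  flipped <- model
  flipped$joint_scores[, 1] <- -flipped$joint_scores[, 1]
  for (b in flipped$block_names) {
    flipped$joint_loadings[[b]][, 1] <- -flipped$joint_loadings[[b]][, 1]
  }
  o1 <- orient_model(model, groups)
  o2 <- orient_model(flipped, groups)
  expect_equal(o1$joint_scores, o2$joint_scores)
  expect_equal(o1$joint_loadings, o2$joint_loadings)
  expect_gt(mean(o1$joint_scores[groups == "ANG", 1]),
            mean(o1$joint_scores[groups == "SHAM", 1]))
  # idempotent
  o3 <- orient_model(o1, groups)
  expect_equal(o3$joint_scores, o1$joint_scores)
  expect_error(orient_model(model, rep("SHAM", 31)), "ANG")
})

test_that("independent blocks show no joint structure beyond the permutation null", {
  set.seed(29)
  m <- 31
  x1 <- scale(matrix(rnorm(m * 20), m, 20))
  x2 <- scale(matrix(rnorm(m * 20), m, 20))
  model <- fit_moca(x1, x2, n_joint = 1L, n_unique = c(0L, 0L))
  r2_obs <- model$r2[[1]]$joint[1]
  null_r2 <- replicate(60, {
    mp <- fit_moca(x1[sample(m), ], x2, n_joint = 1L, n_unique = c(0L, 0L))
    mp$r2[[1]]$joint[1]
  })
  expect_lt(r2_obs, quantile(null_r2, 0.95) + 0.02)
})

test_that("model serialization writes the full table bundle", {
  set.seed(31)
  x1 <- scale(matrix(rnorm(31 * 8), 31, 8))
  x2 <- scale(matrix(rnorm(31 * 6), 31, 6))
  model <- fit_moca(x1, x2, n_joint = 2L, n_unique = c(1L, 0L),
                    block_names = c("plasma", "aorta"))
  dir <- withr::local_tempdir()
  write_moca(model, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "scores.tsv", "loadings_plasma.tsv", "loadings_aorta.tsv",
    "variance.tsv", "metadata.txt"
  )))))
  v <- read.delim(file.path(dir, "variance.tsv"))
  expect_equal(sum(v$r2_pct[v$block == "plasma"]), 100, tolerance = 1e-6)
})
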