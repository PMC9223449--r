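# Multiblock orthogonal component analysis (MOCA) for two blocks: an
# O2PLS/OnPLS-style decomposition splitting each scaled block into a joint
# part (shared across blocks, one consensus score per sample), a
# block-unique part, and residual noise.
#
# Construction, per joint component:
#   1. leading singular-vector pair (w1, w2) of the cross-product X1' X2;
#   2. block scores t1 = X1 w1, t2 = X2 w2, with t2 sign-aligned to t1;
#   3. consensus score t_j = leading left singular vector of [t1 | t2]
#      (unit norm, sign-aligned to t1);
#   4. least-squares deflation of both blocks on t_j.
# Unique components are principal components of each block's deflated
# residual; deflation makes the residual orthogonal to every joint score,
# so unique scores are orthogonal to joint scores by construction.

#' Mean-center and unit-variance scale paired data blocks
#'
#' Both blocks must carry the same samples in the same order. Columns are
#' centered and scaled to unit sample variance (denominator m - 1), the
#' standard pretreatment before latent-variable modelling of metabolomics
#' concentration tables.
#'
#' @param blocks list of two [conc_block()]s (or plain numeric matrices).
#' @param center,unit_variance logical; defaults `TRUE`.
#' @return list with `matrices` (list of scaled matrices) and `scaling`
#'   (per block: `center` and `scale` vectors).
#' @export
scale_blocks <- function(blocks, center = TRUE, unit_variance = TRUE) {
  stopifnot(is.list(blocks), length(blocks) == 2L)
  mats <- lapply(blocks, function(b) {
    if (inherits(b, "conc_block")) {
      if (!all(b$valid_mask)) {
        stop("block has out-of-range cells; impute before scaling")
      }
      b$values
    } else as.matrix(b)
  })
  ids <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (inherits(b, "conc_block")) b$samples$sample_id else rownames(mats[[i]])
  })
  if (nrow(mats[[1]]) != nrow(mats[[2]])) stop("blocks have different sample counts")
  if (!is.null(ids[[1]]) && !is.null(ids[[2]]) &&
      !identical(ids[[1]], ids[[2]])) {
    stop("blocks carry different sample sets or orders")
  }
  scaling <- vector("list", 2L)
  for (i in 1:2) {
    x <- mats[[i]]
    mu <- if (center) colMeans(x) else rep(0, ncol(x))
    x <- sweep(x, 2L, mu, "-")
    sdv <- if (unit_variance) apply(x, 2L, stats::sd) else rep(1, ncol(x))
    if (unit_variance && any(sdv < .Machine$double.eps^0.5)) {
      stop("constant column(s): ",
           paste(colnames(x)[sdv < .Machine$double.eps^0.5], collapse = ", "))
    }
    mats[[i]] <- sweep(x, 2L, sdv, "/")
    scaling[[i]] <- list(center = mu, scale = sdv)
  }
  names(mats) <- names(scaling) <-
    names(blocks) %||% c("block1", "block2")
  list(matrices = mats, scaling = scaling,
       center = center, unit_variance = unit_variance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.leading_sv_pair <- function(C) {
  s <- svd(C, nu = 1L, nv = 1L)
  list(w1 = s$u[, 1L], w2 = s$v[, 1L], d = s$d[1L])
}

#' Fit a two-block joint/unique decomposition
#'
#' @param x1,x2 scaled matrices (same rows = same samples), e.g. from
#'   [scale_blocks()].
#' @param n_joint number of joint components (default 2).
#' @param n_unique integer vector of length 2 (unique components per
#'   block), or `"auto"` to choose each count by a permutation-null test
#'   on the residual's leading eigenvalue (components retained while their
#'   eigenvalue exceeds the null's 95th percentile).
#' @param max_unique cap on auto-selected unique components per block.
#' @param n_perm permutations for the auto rule.
#' @param block_names labels for the two blocks.
#' @return object of class `moca_model`: consensus `joint_scores`
#'   (m x n_joint, columns unit norm), per-block `joint_loadings`,
#'   `unique_scores`/`unique_loadings`, and per-block variance bookkeeping
#'   `r2` with elements `joint`, `unique` (per-component proportions) and
#'   `residual` summing to 1.
#' @export
fit_moca <- function(x1, x2, n_joint = 2L, n_unique = "auto",
                     max_unique = 5L, n_perm = 99L,
                     block_names = c("block1", "block2")) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (nrow(x1) != nrow(x2)) stop("blocks must have the same samples (rows)")
  m <- nrow(x1)
  if (n_joint < 1L) stop("n_joint must be >= 1")
  rank_cap <- min(m - 1L, ncol(x1), ncol(x2))
  if (n_joint > rank_cap) {
    stop("n_joint exceeds the rank of the cross-product (max ", rank_cap, ")")
  }
  ss_tot <- c(sum(x1^2), sum(x2^2))

  Tj <- matrix(0, m, n_joint)
  P <- list(matrix(0, ncol(x1), n_joint), matrix(0, ncol(x2), n_joint))
  r1 <- x1; r2 <- x2
  for (a in seq_len(n_joint)) {
    sv <- .leading_sv_pair(crossprod(r1, r2))
    if (sv$d < 1e-12 * max(1, sqrt(ss_tot[1] * ss_tot[2]))) {
      stop("cross-product rank exhausted at joint component ", a)
    }
    t1 <- r1 %*% sv$w1
    t2 <- r2 %*% sv$w2
    if (sum(t1 * t2) < 0) t2 <- -t2
    tj <- svd(cbind(t1, t2), nu = 1L, nv = 0L)$u[, 1L]
    # deterministic, column-order-invariant sign before group orientation:
    # the largest-magnitude score entry is made positive
    if (tj[which.max(abs(tj))] < 0) tj <- -tj
    p1 <- crossprod(r1, tj) / sum(tj^2)
    p2 <- crossprod(r2, tj) / sum(tj^2)
    r1 <- r1 - tcrossprod(tj, p1)
    r2 <- r2 - tcrossprod(tj, p2)
    Tj[, a] <- tj
    P[[1]][, a] <- p1
    P[[2]][, a] <- p2
  }

  resids <- list(r1, r2)
  if (identical(n_unique, "auto")) {
    n_unique <- vapply(resids, .select_unique_count, integer(1L),
                       max_unique = max_unique, n_perm = n_perm)
  }
  n_unique <- as.integer(rep(n_unique, length.out = 2L))

  unique_scores <- unique_loadings <- vector("list", 2L)
  r2_tab <- vector("list", 2L)
  for (b in 1:2) {
    rb <- resids[[b]]
    nu <- min(n_unique[b], max(0L, min(dim(rb)) - 1L))
    if (nu > 0L) {
      s <- svd(rb, nu = nu, nv = nu)
      u_scores <- s$u[, seq_len(nu), drop = FALSE] %*%
        diag(s$d[seq_len(nu)], nu)
      u_load <- s$v[, seq_len(nu), drop = FALSE]
      # residual after joint deflation is orthogonal to every joint score,
      # hence so are its principal-component scores; re-orthogonalize to
      # clean up floating-point leakage only
      u_scores <- u_scores -
        Tj %*% (crossprod(Tj, u_scores) / colSums(Tj^2))
      rb <- rb - tcrossprod(u_scores, u_load)
    } else {
      u_scores <- matrix(0, m, 0L)
      u_load <- matrix(0, ncol(resids[[b]]), 0L)
    }
    unique_scores[[b]] <- u_scores
    unique_loadings[[b]] <- u_load
    r2_joint <- colSums(Tj^2) * colSums(P[[b]]^2) / ss_tot[b]
    r2_uni <- if (ncol(u_scores) > 0L) {
      colSums(u_scores^2) * colSums(u_load^2) / ss_tot[b]
    } else numeric(0)
    r2_tab[[b]] <- list(joint = r2_joint, unique = r2_uni,
                        residual = sum(rb^2) / ss_tot[b])
  }

  dn1 <- colnames(x1) %||% paste0("v", seq_len(ncol(x1)))
  dn2 <- colnames(x2) %||% paste0("v", seq_len(ncol(x2)))
  rownames(P[[1]]) <- dn1; rownames(P[[2]]) <- dn2
  rownames(unique_loadings[[1]]) <- dn1
  rownames(unique_loadings[[2]]) <- dn2
  colnames(Tj) <- paste0("tj", seq_len(n_joint))
  names(P) <- names(unique_scores) <- names(unique_loadings) <-
    names(r2_tab) <- block_names

  structure(
    list(joint_scores = Tj, joint_loadings = P,
         unique_scores = unique_scores, unique_loadings = unique_loadings,
         r2 = r2_tab, n_joint = n_joint, n_unique = n_unique,
         block_names = block_names, m = m, oriented = FALSE),
    class = "moca_model"
  )
}

# Sequential permutation test: retain a residual PC while its leading
# eigenvalue exceeds the 95th percentile of the eigenvalue obtained after
# independently permuting each column (which destroys inter-column
# correlation but keeps marginals).
.select_unique_count <- function(r, max_unique, n_perm, level = 0.95) {
  count <- 0L
  while (count < max_unique && min(dim(r)) - 1L > 0L) {
    s <- svd(r, nu = 1L, nv = 1L)
    if (s$d[1L] < 1e-10) break
    null_ev <- vapply(seq_len(n_perm), function(i) {
      rp <- apply(r, 2L, sample)
      svd(rp, nu = 0L, nv = 0L)$d[1L]
    }, numeric(1L))
    if (s$d[1L] <= stats::quantile(null_ev, level)) break
    r <- r - s$d[1L] * tcrossprod(s$u[, 1L], s$v[, 1L])
    count <- count + 1L
  }
  count
}

#' @export
print.moca_model <- function(x, ...) {
  cat(sprintf("<moca_model> %d samples, %d joint + (%s) unique components%s\n",
              x$m, x$n_joint, paste(x$n_unique, collapse = ", "),
              if (x$oriented) ", oriented" else ""))
  print(variance_table(x))
  invisible(x)
}

#' Per-component, per-block variance-explained table
#'
#' @param model a [fit_moca()] model.
#' @return data frame with columns `component`, `block`, `r2_pct`; joint
#'   rows, unique rows, and a residual row per block, summing to 100 per
#'   block.
#' @export
variance_table <- function(model) {
  stopifnot(inherits(model, "moca_model"))
  rows <- list()
  for (b in model$block_names) {
    r2 <- model$r2[[b]]
    rows[[length(rows) + 1L]] <- data.frame(
      component = c(
        paste0("joint_", seq_along(r2$joint)),
        if (length(r2$unique)) paste0("unique_", seq_along(r2$unique)),
        "residual"
      ),
      block = b,
      r2_pct = 100 * c(r2$joint, r2$unique, r2$residual),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Orient the first joint component along increasing aneurysmal risk
#'
#' The singular-vector sign is arbitrary; this pins the display/reporting
#' convention so the aneurysm group scores positive: if
#' `mean(tj1 | ANG) <= mean(tj1 | SHAM)`, the first joint score column and
#' both blocks' first joint loading columns are negated.
#'
#' @param model a [fit_moca()] model.
#' @param groups factor/character of group labels (SHAM/HCD/ANG), one per
#'   sample, in the model's row order.
#' @return the oriented model (`oriented = TRUE`).
#' @export
orient_model <- function(model, groups) {
  stopifnot(inherits(model, "moca_model"),
            length(groups) == model$m)
  groups <- as.character(groups)
  for (g in c("SHAM", "ANG")) {
    if (!any(groups == g)) stop("required group absent: ", g)
  }
  tj1 <- model$joint_scores[, 1L]
  if (mean(tj1[groups == "ANG"]) <= mean(tj1[groups == "SHAM"])) {
    model$joint_scores[, 1L] <- -model$joint_scores[, 1L]
    for (b in model$block_names) {
      model$joint_loadings[[b]][, 1L] <- -model$joint_loadings[[b]][, 1L]
    }
  }
  model$oriented <- TRUE
  model
}

#' Reconstruct a block from its model parts
#'
#' Returns the joint part, unique part, and their sum's residual relative
#' to the supplied scaled matrix; `joint + unique + residual` equals the
#' input exactly up to floating-point error.
#'
#' @param model a [fit_moca()] model.
#' @param block block name.
#' @param x the scaled matrix that was fitted (needed for the residual).
#' @return list of matrices `joint`, `unique`, `residual`.
#' @export
reconstruct_block <- function(model, block, x) {
  stopifnot(inherits(model, "moca_model"), block %in% model$block_names)
  joint <- tcrossprod(model$joint_scores, model$joint_loadings[[block]])
  uniq <- tcrossprod(model$unique_scores[[block]],
                     model$unique_loadings[[block]])
  list(joint = joint, unique = uniq, residual = as.matrix(x) - joint - uniq)
}

#' Serialize a fitted model to a directory of delimited tables
#'
#' Writes `scores.tsv` (joint + unique scores), `loadings_<block>.tsv`,
#' `variance.tsv` and `metadata.txt` (component counts, orientation flag).
#'
#' @param model a [fit_moca()] model.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_moca <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- as.data.frame(model$joint_scores)
  for (b in model$block_names) {
    us <- model$unique_scores[[b]]
    if (ncol(us)) {
      colnames(us) <- paste0("tu_", b, "_", seq_len(ncol(us)))
      sc <- cbind(sc, as.data.frame(us))
    }
  }
  utils::write.table(sc, file.path(dir, "scores.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (b in model$block_names) {
    ld <- cbind(
      data.frame(metabolite = rownames(model$joint_loadings[[b]]),
                 stringsAsFactors = FALSE),
      as.data.frame(model$joint_loadings[[b]]) |>
        stats::setNames(paste0("pj", seq_len(model$n_joint)))
    )
    utils::write.table(ld, file.path(dir, paste0("loadings_", b, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(variance_table(model), file.path(dir, "variance.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(c(
    sprintf("n_joint: %d", model$n_joint),
    sprintf("n_unique: %s", paste(model$n_unique, collapse = ",")),
    sprintf("oriented: %s", model$oriented),
    sprintf("samples: %d", model$m)
  ), file.path(dir, "metadata.txt"))
  invisible(dir)
}
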