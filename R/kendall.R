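# Kendall tau-b rank correlation with an exact small-sample null and a
# tie-corrected normal approximation, plus Benjamini-Hochberg step-up
# selection.

# Null distribution of the Kendall statistic S = concordant - discordant
# for n untied observations: S = n0 - 2*D where D is the number of
# inversions of a uniform random permutation; counts of permutations with
# D = k follow the Mahonian recursion (convolution of uniform blocks).
.inversion_counts <- function(n) {
  w <- 1
  for (j in 2:n) {
    # convolve with a length-j block of ones
    cs <- cumsum(c(w, rep(0, j - 1L)))
    w <- cs - c(rep(0, j), cs[seq_len(length(cs) - j)])
  }
  w  # counts for D = 0 .. n(n-1)/2; sums to n!
}

#' Kendall tau-b correlation with p-value
#'
#' Computes the tie-corrected tau-b statistic. The two-sided p-value is
#' exact (from the permutation-null distribution of the concordance
#' statistic, equivalent to full enumeration) for `n <= exact_max` when
#' neither vector has ties; otherwise a normal approximation with the
#' standard tie-corrected variance is used.
#'
#' @param x,y numeric vectors of equal length (>= 3), not constant.
#' @param exact_max largest untied sample size for which the exact null is
#'   used (default 9).
#' @return list with `tau`, `p_value`, `S` (concordant minus discordant,
#'   tie-weighted), and `method` (`"exact"` or `"normal"`).
#' @export
kendall_tau <- function(x, y, exact_max = 9L) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            is.numeric(x), is.numeric(y), !anyNA(x), !anyNA(y))
  n <- length(x)
  if (min(x) == max(x) || min(y) == max(y)) {
    stop("Kendall tau undefined for a constant vector")
  }
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  S <- sum(dx[lower.tri(dx)] * dy[lower.tri(dy)])
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))

  no_ties <- n1 == 0 && n2 == 0
  if (no_ties && n <= exact_max) {
    counts <- .inversion_counts(n)
    s_vals <- n0 - 2 * (seq_along(counts) - 1L)  # S for D = 0,1,...
    p <- sum(counts[abs(s_vals) >= abs(S) - 1e-9]) / factorial(n)
    method <- "exact"
  } else {
    tt <- as.numeric(tx); uu <- as.numeric(ty)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tt * (tt - 1) * (2 * tt + 5))
    vu <- sum(uu * (uu - 1) * (2 * uu + 5))
    v1 <- sum(tt * (tt - 1)) * sum(uu * (uu - 1)) / (2 * n * (n - 1))
    v2 <- sum(tt * (tt - 1) * (tt - 2)) * sum(uu * (uu - 1) * (uu - 2)) /
      (9 * n * (n - 1) * (n - 2))
    v <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(tau = tau, p_value = min(1, p), S = S, method = method)
}

#' Benjamini-Hochberg step-up selection
#'
#' Finds the largest `k` with sorted `p_(k) <= k * q / m` and flags every
#' p-value at or below that admissible threshold (`alpha_threshold`,
#' reported as 0 when nothing passes).
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @param q target false-discovery rate (default 0.05).
#' @return list with `significant` (logical mask in input order),
#'   `alpha_threshold`, `n_significant`, `q`.
#' @export
bh_select <- function(p_values, q = 0.05) {
  stopifnot(length(p_values) > 0, all(p_values >= 0 & p_values <= 1),
            q > 0, q < 1)
  m <- length(p_values)
  ord <- sort(p_values)
  ok <- which(ord <= seq_len(m) * q / m)
  if (length(ok) == 0L) {
    return(list(significant = rep(FALSE, m), alpha_threshold = 0,
                n_significant = 0L, q = q))
  }
  thr <- ord[max(ok)]
  mask <- p_values <= thr
  list(significant = mask, alpha_threshold = thr,
       n_significant = sum(mask), q = q)
}
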