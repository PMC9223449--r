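# Shared fixtures and independent brute-force oracles.

# Small block built from an explicit matrix; metabolite names default to
# two amino acids + one PC so the name grammar always resolves.
toy_block <- function(values, groups = NULL, tissue = "plasma",
                      weights = NULL, mask = NULL,
                      met_names = NULL) {
  values <- as.matrix(values)
  m <- nrow(values)
  if (is.null(groups)) groups <- rep(c("SHAM", "HCD", "ANG"), length.out = m)
  if (is.null(met_names)) {
    met_names <- c("Gly", "Leu", "PC aa C36:2", "lysoPC a C18:1",
                   "SM C16:0", "C2")[seq_len(ncol(values))]
  }
  colnames(values) <- met_names
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(m)),
                        group = groups, stringsAsFactors = FALSE)
  if (tissue == "aorta") {
    samples$aorta_weight_mg <- weights %||% rep(5, m)
  }
  conc_block(values, samples, parse_metabolite_names(met_names),
             mask, tissue = tissue)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All permutations of 1..n (n small), one per row.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Brute-force Kendall statistic S = concordant - discordant over all pairs.
brute_kendall_S <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  s
}

# Exact two-sided Kendall p by full enumeration of rank permutations
# (untied data): P(|S| >= |S_obs|) under a uniform random permutation.
brute_kendall_p <- function(x, y) {
  n <- length(x)
  s_obs <- brute_kendall_S(x, y)
  pm <- all_perms(n)
  s_all <- apply(pm, 1L, function(p) brute_kendall_S(seq_len(n), p))
  mean(abs(s_all) >= abs(s_obs) - 1e-9)
}

# Brute-force BH: largest k with sorted p_(k) <= k q / m, reject p <= p_(k).
brute_bh_mask <- function(p, q) {
  m <- length(p)
  sp <- sort(p)
  k <- 0
  for (i in seq_len(m)) if (sp[i] <= i * q / m) k <- i
  if (k == 0) rep(FALSE, m) else p <= sp[k]
}

# Brute-force AUC by exhaustive pair counting (ties score 1/2).
brute_auc <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}
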