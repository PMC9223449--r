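# Synthetic two-block cohort generator: a shared latent "aneurysmal risk"
# factor ordering three groups, one block-unique factor per tissue,
# class-structured lognormal concentrations, a planted signature of
# up/down metabolites per block, and low-end LOD censoring. Provides
# ground truth for every pipeline stage; the real study data are not
# deposited.

# Log-scale baseline medians (uM) per class; targeted panels span orders
# of magnitude, which makes unit-variance scaling a meaningful step.
.CLASS_BASELINE_UM <- c(
  hexose = 5000, aminoacid = 200, biogenic_amine = 5,
  phosphatidylcholine = 50, lysophosphatidylcholine = 3,
  sphingomyelin = 30, acylcarnitine = 1
)

#' Planted metabolite signature of aneurysmal risk
#'
#' Directions (+1 rises with risk, -1 falls) per block. Plasma: BCAA,
#' several other amino acids, putrescine and the PC/SM/lysoPC classes plus
#' long-chain acylcarnitines rise; glycine, glutamine, taurine, free
#' carnitine and the shortest acylcarnitines fall. Aorta: ADMA,
#' putrescine, ornithine and related amino acids plus unsaturated lysoPC
#' rise; PC, SM, saturated lysoPC, hexoses and several polar metabolites
#' fall. Class- or rule-level targets are applied first, then
#' metabolite-level rows override them.
#'
#' @return data frame with columns `block`, `target` (metabolite name or
#'   [resolve_rule()] rule name prefixed by nothing), `direction`.
#' @export
default_signature <- function() {
  # class-wide trends are subtler (magnitude 0.3) than the named
  # metabolites (magnitude 1); directions are pinned, magnitudes are the
  # generator's free parameters
  rbind(
    data.frame(block = "plasma",
               target = c("PC", "SM", "lysoPC", "LCAC"),
               direction = 1, magnitude = 0.3),
    data.frame(block = "plasma",
               target = c("Leu", "Ile", "Val", "Phe", "Trp", "Thr", "Met",
                          "alpha-AAA", "Putrescine"),
               direction = 1, magnitude = 1),
    data.frame(block = "plasma",
               target = c("Gly", "Gln", "Taurine", "C0", "C2", "C3"),
               direction = -1, magnitude = 1),
    data.frame(block = "aorta",
               target = c("PC", "SM", "lysoPC_sat"),
               direction = -1, magnitude = 0.3),
    data.frame(block = "aorta",
               target = c("lysoPC_unsat"),
               direction = 1, magnitude = 0.3),
    data.frame(block = "aorta",
               target = c("ADMA", "Putrescine", "Orn", "Lys", "alpha-AAA",
                          "Trp", "His", "Cit", "t4-OH-Pro"),
               direction = 1, magnitude = 1),
    data.frame(block = "aorta",
               target = c("Taurine", "Gly", "C0", "C2", "C3", "Leu",
                          "Tyr", "Met", "Carnosine", "H1"),
               direction = -1, magnitude = 1)
  )
}

#' Cohort generator specification
#'
#' Defaults emulate the study design: 31 mice (SHAM 11, HCD 10, ANG 10),
#' a 188-analyte p180-style panel measured in both plasma and aorta, a
#' latent risk factor with group means (-1, 0, +1) and within-group sd
#' 0.3, per-metabolite log-scale variance split 40% joint / 30% block-
#' unique / 30% noise, log-sd 0.35, 2% low-end LOD censoring per
#' metabolite, and aorta wet weights lognormal around 5 mg.
#'
#' @param n_per_group named counts for SHAM/HCD/ANG.
#' @param panel metabolite descriptor data frame.
#' @param joint_effect per-group mean of the latent risk factor.
#' @param within_sd within-group sd of the risk factor.
#' @param fracs variance fractions `c(joint, unique, noise)`, summing to 1.
#' @param sigma_log total log-scale sd per metabolite.
#' @param signature planted direction table, see [default_signature()].
#' @param lod_quantile fraction of each metabolite's lowest values
#'   censored as below-LOD.
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(SHAM = 11L, HCD = 10L, ANG = 10L),
                        panel = default_panel(),
                        joint_effect = c(SHAM = -1, HCD = 0, ANG = 1),
                        within_sd = 0.3,
                        fracs = c(joint = 0.4, unique = 0.3, noise = 0.3),
                        sigma_log = 0.35,
                        signature = default_signature(),
                        lod_quantile = 0.02,
                        seed = 1L) {
  stopifnot(
    all(c("SHAM", "HCD", "ANG") %in% names(n_per_group)),
    abs(sum(fracs) - 1) < 1e-12, all(fracs >= 0),
    !is.unsorted(joint_effect[c("SHAM", "HCD", "ANG")]),
    lod_quantile >= 0, lod_quantile < 1, sigma_log > 0
  )
  structure(
    list(n_per_group = n_per_group, panel = panel,
         joint_effect = joint_effect, within_sd = within_sd,
         fracs = fracs, sigma_log = sigma_log, signature = signature,
         lod_quantile = lod_quantile, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Signed-magnitude vector per block: random unit baseline, then signature
# rules (class/rule rows first), then metabolite-level overrides. The
# background (untargeted) signs are then rebalanced so the block's net
# signed loading is as close to zero as parity allows: a risk factor that
# shifted total metabolite content would be confounded with the
# sample-level dilution factor, so a well-posed planted signature is kept
# approximately total-preserving.
.signature_signs <- function(panel, signature, block) {
  signs <- sample(c(-1, 1), nrow(panel), replace = TRUE)
  targeted <- rep(FALSE, nrow(panel))
  sig <- signature[signature$block == block, , drop = FALSE]
  if (is.null(sig$magnitude)) sig$magnitude <- 1
  is_rule <- sig$target %in% names(.BUILTIN_RULES) &
    !(sig$target %in% panel$name)
  for (i in which(is_rule)) {
    sel <- resolve_rule(panel, sig$target[i])
    signs[sel] <- sig$direction[i] * sig$magnitude[i]
    targeted <- targeted | sel
  }
  for (i in which(!is_rule)) {
    sel <- panel$name == sig$target[i]
    signs[sel] <- sig$direction[i] * sig$magnitude[i]
    targeted <- targeted | sel
  }
  bg <- which(!targeted)
  for (j in sample(bg)) {
    if (abs(sum(signs) - 2 * signs[j]) < abs(sum(signs))) {
      signs[j] <- -signs[j]
    }
  }
  names(signs) <- panel$name
  signs
}

.standardize <- function(v) (v - mean(v)) / stats::sd(v)

#' Generate a synthetic two-block cohort
#'
#' Log-scale model per metabolite j and mouse i in block b:
#' `z_ij = log(baseline_class) + risk_i * lambda_bj + u_bi * mu_bj + e_ij`,
#' exponentiated to lognormal concentrations. `risk` is the shared latent
#' factor (standardized in-sample); `u_b` is a block-unique sample-level
#' systematic factor (dilution / tissue-amount-like, common-sign loadings)
#' orthogonalized against `risk`; loading magnitudes place `fracs` of each
#' metabolite's log variance on the joint, unique and noise parts, with
#' joint signs from the planted signature. The aorta block is planted in
#' per-mg space and multiplied back by lognormal wet weights, so
#' [normalize_by_weight()] recovers the planted matrix exactly. The
#' lowest `lod_quantile` of each metabolite's measured values are marked
#' below-LOD. Identical spec and seed give identical output.
#'
#' @param spec a [cohort_spec()].
#' @return list with `plasma` and `aorta` [conc_block()]s and `truth`
#'   (risk factor, per-block planted signs, spec echo).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  npg <- spec$n_per_group[c("SHAM", "HCD", "ANG")]
  m <- sum(npg)
  groups <- rep(names(npg), npg)
  sample_id <- sprintf("mouse_%02d", seq_len(m))

  risk <- .standardize(
    spec$joint_effect[groups] + stats::rnorm(m, 0, spec$within_sd)
  )
  panel <- spec$panel
  k <- nrow(panel)
  base_log <- log(.CLASS_BASELINE_UM[panel$class])

  other_factors <- risk
  make_block_values <- function(block) {
    signs <- .signature_signs(panel, spec$signature, block)
    # signed magnitudes are normalized so the block-level joint energy is
    # exactly the joint variance fraction of the block's total variance
    lambda <- signs * sqrt(spec$fracs["joint"] * k / sum(signs^2)) *
      spec$sigma_log
    # the block-unique factor is made exactly uncorrelated in-sample with
    # the risk factor and with the other block's unique factor: blocks
    # share only the planted joint structure, so the ground truth stays
    # identifiable at cohort size
    u <- .standardize(stats::residuals(
      stats::lm(stats::rnorm(m) ~ other_factors)
    ))
    other_factors <<- cbind(other_factors, u)
    # block-unique structure modelled as a sample-level systematic factor
    # (dilution / tissue-amount-like): equal loadings across the panel,
    # which is exactly the nuisance ratio biomarkers cancel
    mu <- rep(sqrt(spec$fracs["unique"]) * spec$sigma_log, k)
    eps <- matrix(stats::rnorm(m * k, 0,
                               sqrt(spec$fracs["noise"]) * spec$sigma_log),
                  m, k)
    z <- matrix(base_log, m, k, byrow = TRUE) +
      outer(risk, lambda) + outer(u, mu) + eps
    list(values = exp(z), signs = signs, unique_factor = u)
  }

  censor <- function(values) {
    mask <- matrix(TRUE, nrow(values), ncol(values))
    n_cens <- round(spec$lod_quantile * nrow(values))
    if (n_cens > 0L) {
      for (j in seq_len(ncol(values))) {
        mask[order(values[, j])[seq_len(n_cens)], j] <- FALSE
      }
    }
    mask
  }

  pl <- make_block_values("plasma")
  ao <- make_block_values("aorta")
  weights <- exp(stats::rnorm(m, log(5), 0.15))  # aorta wet weight, mg
  ao_raw <- ao$values * weights                  # uM measured on tissue

  pl_mask <- censor(pl$values)
  ao_mask <- censor(ao_raw)

  plasma <- conc_block(
    pl$values,
    data.frame(sample_id = sample_id, group = groups,
               stringsAsFactors = FALSE),
    panel, pl_mask, tissue = "plasma"
  )
  aorta <- conc_block(
    ao_raw,
    data.frame(sample_id = sample_id, group = groups,
               aorta_weight_mg = weights, stringsAsFactors = FALSE),
    panel, ao_mask, tissue = "aorta"
  )
  list(
    plasma = plasma, aorta = aorta,
    truth = list(risk = stats::setNames(risk, sample_id),
                 groups = groups,
                 signs = list(plasma = pl$signs, aorta = ao$signs),
                 spec = spec)
  )
}

#' Generate a null cohort with no shared structure
#'
#' Same generator with the joint variance fraction set to zero (its share
#' moved to noise); used for FDR and permutation-null checks.
#'
#' @param spec a [cohort_spec()].
#' @return as [generate_cohort()].
#' @export
null_cohort <- function(spec = cohort_spec()) {
  spec$fracs <- c(joint = 0,
                  unique = unname(spec$fracs["unique"]),
                  noise = unname(spec$fracs["noise"] + spec$fracs["joint"]))
  generate_cohort(spec)
}
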