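# Pairwise nonparametric group comparisons, biochemical class sums and
# ratios, and ROC/AUC biomarker evaluation with DeLong confidence
# intervals.

# Built-in selection rules against the panel taxonomy. LCAC follows the
# "more than 12 carbons" definition (strict inequality); the
# unsaturated/saturated lysoPC partition is double bonds >= 1 vs == 0.
.BUILTIN_RULES <- list(
  BCAA = function(m) m$name %in% c("Leu", "Ile", "Val"),
  PC = function(m) m$class == "phosphatidylcholine",
  lysoPC = function(m) m$class == "lysophosphatidylcholine",
  SM = function(m) m$class == "sphingomyelin",
  acylcarnitine = function(m) m$class == "acylcarnitine",
  total_carnitine = function(m) m$class == "acylcarnitine",
  LCAC = function(m) m$class == "acylcarnitine" &
    !is.na(m$acyl_carbons) & m$acyl_carbons > 12,
  "C2+C3" = function(m) m$name %in% c("C2", "C3"),
  lysoPC_unsat = function(m) m$class == "lysophosphatidylcholine" &
    m$acyl_double_bonds >= 1,
  lysoPC_sat = function(m) m$class == "lysophosphatidylcholine" &
    m$acyl_double_bonds == 0
)

#' Resolve a metabolite selection rule
#'
#' A rule is a built-in name (`"BCAA"`, `"PC"`, `"lysoPC"`, `"SM"`,
#' `"LCAC"`, `"total_carnitine"`, `"C2+C3"`, `"lysoPC_unsat"`,
#' `"lysoPC_sat"`, `"acylcarnitine"`), a character vector of metabolite
#' names, or a predicate function over the descriptor data frame.
#'
#' @param metabolites descriptor data frame.
#' @param rule the rule.
#' @return logical selection vector; errors if it matches nothing.
#' @export
resolve_rule <- function(metabolites, rule) {
  sel <- if (is.function(rule)) {
    rule(metabolites)
  } else if (is.character(rule) && length(rule) == 1L &&
             rule %in% names(.BUILTIN_RULES)) {
    .BUILTIN_RULES[[rule]](metabolites)
  } else if (is.character(rule)) {
    missing <- setdiff(rule, metabolites$name)
    if (length(missing)) {
      stop("metabolites not in panel: ", paste(missing, collapse = ", "))
    }
    metabolites$name %in% rule
  } else stop("unsupported rule type")
  sel[is.na(sel)] <- FALSE
  if (!any(sel)) stop("rule matches no metabolite")
  sel
}

#' Per-sample biochemical class sum
#'
#' @param block a [conc_block()] (fully valid; impute first).
#' @param rule selection rule, see [resolve_rule()].
#' @return named numeric vector (one sum per sample) in the block's units.
#' @export
class_sum <- function(block, rule) {
  stopifnot(inherits(block, "conc_block"))
  sel <- resolve_rule(block$metabolites, rule)
  rowSums(block$values[, sel, drop = FALSE])
}

#' Ratio biomarker specification
#'
#' @param name display name.
#' @param numerator,denominator selection rules ([resolve_rule()]).
#' @return object of class `ratio_spec`.
#' @export
ratio_spec <- function(name, numerator, denominator = NULL) {
  structure(list(name = name, numerator = numerator,
                 denominator = denominator), class = "ratio_spec")
}

#' Candidate biomarkers evaluated in the reference analysis
#'
#' Plasma: BCAA (sum), BCAA/Gly, BCAA/Gln. Aorta: PC/SM, LysoPC/PC and the
#' unsaturated-to-saturated lysoPC ratio (phospholipase A1 vs A2 activity
#' index).
#'
#' @return named list: per tissue, a list of [ratio_spec()]s.
#' @export
default_biomarker_specs <- function() {
  list(
    plasma = list(
      ratio_spec("BCAA", "BCAA"),
      ratio_spec("BCAA/Gly", "BCAA", "Gly"),
      ratio_spec("BCAA/Gln", "BCAA", "Gln")
    ),
    aorta = list(
      ratio_spec("PC/SM", "PC", "SM"),
      ratio_spec("LysoPC/PC", "lysoPC", "PC"),
      ratio_spec("LysoPC U/S", "lysoPC_unsat", "lysoPC_sat")
    )
  )
}

#' Per-sample ratio (or sum) statistic
#'
#' Numerator sum over denominator sum, element-wise per sample; with a
#' `NULL` denominator, just the numerator sum. Unit-free whenever the
#' denominator is present.
#'
#' @param block a [conc_block()].
#' @param spec a [ratio_spec()].
#' @return named numeric vector, one value per sample.
#' @export
ratio_statistic <- function(block, spec) {
  stopifnot(inherits(spec, "ratio_spec"))
  num <- class_sum(block, spec$numerator)
  if (is.null(spec$denominator)) return(num)
  den <- class_sum(block, spec$denominator)
  if (any(den <= 0)) {
    stop("non-positive denominator for sample(s): ",
         paste(block$samples$sample_id[den <= 0], collapse = ", "))
  }
  num / den
}

#' Pairwise Mann-Whitney-Wilcoxon tests across groups
#'
#' Two-sided test per group pair: exact when `min(n1, n2) <= 8` and there
#' are no ties, otherwise the normal approximation with tie correction
#' (no continuity correction). `p_adj` is Benjamini-Hochberg over the
#' returned family of pairs.
#'
#' @param values numeric vector, one value per sample.
#' @param groups factor/character of group labels.
#' @return data frame with columns `group1`, `group2`, `n1`, `n2`, `U`,
#'   `p_value`, `p_adj`.
#' @export
mannwhitney_pairwise <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  lv <- intersect(GROUP_LEVELS, unique(groups))
  if (length(lv) < 2L) lv <- unique(groups)
  if (length(lv) < 2L) stop("need at least two groups")
  cnt <- table(groups)
  if (any(cnt < 2L)) stop("every group needs >= 2 samples")
  pairs <- utils::combn(lv, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    a <- values[groups == pr[1]]
    b <- values[groups == pr[2]]
    exact <- min(length(a), length(b)) <= 8L &&
      !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = FALSE)
    )
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = length(a), n2 = length(b),
               U = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' ROC AUC with a DeLong confidence interval
#'
#' AUC by pair counting with ties scored one half (equal to the
#' Mann-Whitney U over `n_pos * n_neg`); variance by DeLong's
#' placement-value estimator; 95% normal-theory interval on the AUC scale,
#' clipped to `[0, 1]`. When the raw AUC falls below 0.5, the score
#' orientation is flipped (recorded in `flipped`) so that discriminative
#' performance, not direction, is reported.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (logical, 0/1, or two-level factor; the
#'   higher level / `TRUE` / 1 is the positive class).
#' @param conf_level confidence level (default 0.95).
#' @param cutoff AUC threshold for `good_classifier` (default 0.80).
#' @return object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `var_auc`, `n_pos`, `n_neg`, `flipped`, `good_classifier`.
#' @export
roc_auc_delong <- function(scores, labels, conf_level = 0.95,
                           cutoff = 0.80) {
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  if (is.factor(labels)) labels <- labels == levels(labels)[2L]
  pos <- as.logical(labels)
  if (anyNA(pos)) stop("labels must be binary")
  if (!any(pos) || all(pos)) stop("both classes must be present")
  x <- scores[pos]    # positives
  y <- scores[!pos]   # negatives
  psi <- function(xs, ys) {
    0.5 * (sign(outer(xs, ys, "-")) + 1)  # 1 win, 0.5 tie, 0 loss
  }
  M <- psi(x, y)
  auc <- mean(M)
  flipped <- FALSE
  if (auc < 0.5) {
    M <- 1 - M
    auc <- mean(M)
    flipped <- TRUE
  }
  v10 <- rowMeans(M)   # placement values of positives
  v01 <- colMeans(M)   # placement values of negatives
  var_auc <- stats::var(v10) / length(x) + stats::var(v01) / length(y)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- zq * sqrt(var_auc)
  structure(
    list(auc = auc, ci_low = max(0, auc - half),
         ci_high = min(1, auc + half), var_auc = var_auc,
         n_pos = length(x), n_neg = length(y), flipped = flipped,
         conf_level = conf_level,
         good_classifier = auc >= cutoff),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f [%.3f, %.3f] (n+ = %d, n- = %d)%s%s\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg,
              if (x$flipped) ", orientation flipped" else "",
              if (x$good_classifier) ", good classifier" else ""))
  invisible(x)
}

#' Default group contrasts for biomarker evaluation
#'
#' `ANG_vs_rest` pools SHAM and HCD as the negative ("no-ANG") class;
#' `HCD_vs_ANG` and `SHAM_vs_HCD` are the adjacent pairwise contrasts.
#'
#' @return named list: each element has `positive` and `negative` group
#'   label vectors.
#' @export
default_contrasts <- function() {
  list(
    ANG_vs_rest = list(positive = "ANG", negative = c("SHAM", "HCD")),
    HCD_vs_ANG = list(positive = "ANG", negative = "HCD"),
    SHAM_vs_HCD = list(positive = "HCD", negative = "SHAM")
  )
}

#' Evaluate ratio biomarkers across group contrasts
#'
#' Computes each spec's per-sample statistic on its block and a DeLong
#' ROC per contrast. `lci_below_cutoff` flags the reported caveat case:
#' an AUC at or above the cutoff whose lower confidence bound still
#' includes the cutoff.
#'
#' @param block a [conc_block()] (fully valid).
#' @param specs list of [ratio_spec()]s.
#' @param contrasts named list as from [default_contrasts()].
#' @param cutoff AUC performance cutoff (default 0.80).
#' @return data frame: `spec`, `contrast`, `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`, `flipped`, `good_classifier`, `lci_below_cutoff`.
#' @export
evaluate_biomarkers <- function(block, specs,
                                contrasts = default_contrasts(),
                                cutoff = 0.80) {
  groups <- as.character(block$samples$group)
  rows <- list()
  for (sp in specs) {
    stat <- ratio_statistic(block, sp)
    for (cn in names(contrasts)) {
      ct <- contrasts[[cn]]
      sel <- groups %in% c(ct$positive, ct$negative)
      if (!any(groups %in% ct$positive) || !any(groups %in% ct$negative)) {
        stop("contrast ", cn, " has an empty side")
      }
      rr <- roc_auc_delong(stat[sel], groups[sel] %in% ct$positive,
                           cutoff = cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        spec = sp$name, contrast = cn, auc = rr$auc,
        ci_low = rr$ci_low, ci_high = rr$ci_high,
        n_pos = rr$n_pos, n_neg = rr$n_neg, flipped = rr$flipped,
        good_classifier = rr$good_classifier,
        lci_below_cutoff = rr$ci_low < cutoff,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
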