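# Preprocessing: dynamic-range completeness filter, aorta-weight
# normalization, below-LOD imputation.

#' Dynamic-range completeness filter
#'
#' Retains exactly those metabolites whose fraction of in-range
#' measurements is strictly greater than `min_fraction` (the retention
#' rule is "more than 70%", so 7/10 valid is dropped and 8/10 kept at the
#' default). Samples are never removed.
#'
#' @param block a [conc_block()].
#' @param min_fraction retention threshold, strictly between 0 and 1.
#' @return the filtered block, with attribute `"dropped"`: a data frame of
#'   the removed metabolites and their valid fractions.
#' @export
filter_dynamic_range <- function(block, min_fraction = 0.70) {
  stopifnot(inherits(block, "conc_block"),
            min_fraction > 0, min_fraction < 1)
  if (ncol(block$values) == 0L || nrow(block$values) == 0L) {
    stop("empty block")
  }
  frac <- colMeans(block$valid_mask)
  keep <- frac > min_fraction
  dropped <- data.frame(name = block$metabolites$name[!keep],
                        valid_fraction = unname(frac[!keep]),
                        stringsAsFactors = FALSE)
  out <- conc_block(block$values[, keep, drop = FALSE], block$samples,
                    block$metabolites[keep, , drop = FALSE],
                    block$valid_mask[, keep, drop = FALSE],
                    tissue = block$tissue, units = block$units)
  attr(out, "dropped") <- dropped
  out
}

#' Normalize aorta concentrations by tissue wet weight
#'
#' Divides every concentration in a sample's row by that sample's aorta
#' wet weight (mg); units become uM/mg. Extraction volume is constant
#' across samples and is not corrected. The validity mask is unchanged:
#' scaling a row cannot move a measurement in or out of the instrument's
#' dynamic range.
#'
#' @param block an aorta [conc_block()] with positive weights.
#' @return the normalized block (units `uM/mg`).
#' @export
normalize_by_weight <- function(block) {
  stopifnot(inherits(block, "conc_block"))
  if (block$tissue != "aorta") stop("weight normalization applies to aorta blocks")
  w <- block$samples$aorta_weight_mg
  if (is.null(w) || anyNA(w) || any(w <= 0)) stop("missing or non-positive aorta weight")
  conc_block(block$values / w, block$samples, block$metabolites,
             block$valid_mask, tissue = "aorta", units = "uM/mg")
}

#' Impute below-LOD measurements
#'
#' Replaces out-of-range cells per column: `half_min` substitutes half the
#' smallest in-range value of that metabolite (standard targeted-
#' metabolomics practice for left-censored values), `zero` substitutes 0.
#' Intended after [filter_dynamic_range()], which guarantees every
#' retained column has in-range values.
#'
#' @param block a filtered [conc_block()].
#' @param strategy `"half_min"` or `"zero"`.
#' @return block with all cells valid; attribute `"n_imputed"` reports the
#'   number of replaced cells.
#' @export
impute_below_lod <- function(block, strategy = c("half_min", "zero")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(block, "conc_block"))
  vals <- block$values
  mask <- block$valid_mask
  n_imp <- sum(!mask)
  if (n_imp > 0L) {
    for (j in seq_len(ncol(vals))) {
      miss <- !mask[, j]
      if (!any(miss)) next
      if (all(miss)) stop("column '", colnames(vals)[j],
                          "' has no in-range values; filter first")
      vals[miss, j] <- if (strategy == "half_min") {
        min(vals[mask[, j], j]) / 2
      } else 0
    }
  }
  out <- conc_block(vals, block$samples, block$metabolites,
                    matrix(TRUE, nrow(vals), ncol(vals)),
                    tissue = block$tissue, units = block$units)
  attr(out, "n_imputed") <- n_imp
  out
}

#' LDL cholesterol by the Friedewald formula
#'
#' `LDL = CT - HDL - TG/2.2` with all quantities in mmol/L. The formula is
#' unreliable at high triglycerides; a warning is emitted above
#' `tg_warn` (default 4.5 mmol/L).
#'
#' @param ct total cholesterol (mmol/L).
#' @param hdl HDL cholesterol (mmol/L).
#' @param tg triglycerides (mmol/L).
#' @param tg_warn triglyceride validity bound (mmol/L).
#' @return LDL cholesterol (mmol/L).
#' @export
friedewald_ldl <- function(ct, hdl, tg, tg_warn = 4.5) {
  stopifnot(length(ct) == length(hdl), length(hdl) == length(tg))
  if (any(ct < 0 | hdl < 0 | tg < 0)) stop("lipid inputs must be nonnegative")
  if (any(tg > tg_warn)) {
    warning("triglycerides above ", tg_warn,
            " mmol/L: Friedewald estimate unreliable")
  }
  ct - hdl - tg / 2.2
}
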