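# Variable importance on the first joint component: Kendall tau-b between
# each metabolite and the consensus score across mice, BH-selected, with
# 3D-volcano coordinates (loading, tau, -log10 p).

VOLCANO_COLORS <- c(
  phosphatidylcholine = "red",
  sphingomyelin = "yellow",
  lysophosphatidylcholine = "blue",
  acylcarnitine = "violet",
  aminoacid = "green",
  biogenic_amine = "green",
  hexose = "orange"
)

#' Rank metabolites against the first joint component
#'
#' For every metabolite, computes Kendall tau-b (and its p-value) between
#' the metabolite's values across mice and the first joint score, pairs it
#' with the metabolite's loading on that component, and flags significance
#' by Benjamini-Hochberg selection over the whole block at FDR `q`.
#'
#' @param x matrix whose columns are the block's metabolites (rows in the
#'   model's sample order); rank statistics are unaffected by whether the
#'   scaled or unscaled block is supplied.
#' @param model an *oriented* [fit_moca()] model (see [orient_model()]).
#' @param block block name within the model.
#' @param q FDR level for the BH selection (default 0.05).
#' @param classes optional metabolite descriptor data frame (from
#'   [parse_metabolite_names()]) used to attach the class column.
#' @return data frame with columns `metabolite`, `class`, `loading`,
#'   `tau`, `p_value`, `neg_log10_p`, `significant`; attribute `"bh"`
#'   carries the [bh_select()] result.
#' @export
importance_table <- function(x, model, block, q = 0.05, classes = NULL) {
  stopifnot(inherits(model, "moca_model"), block %in% model$block_names)
  if (!model$oriented) {
    stop("model must be oriented (orient_model) before ranking importance")
  }
  x <- as.matrix(x)
  load1 <- model$joint_loadings[[block]][, 1L]
  if (ncol(x) != length(load1)) stop("column count does not match loadings")
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), rownames(model$joint_loadings[[block]]))) {
    stop("column names do not match the model's loading order")
  }
  tj1 <- model$joint_scores[, 1L]
  kt <- apply(x, 2L, function(col) {
    r <- kendall_tau(col, tj1)
    c(r$tau, r$p_value)
  })
  p <- kt[2L, ]
  bh <- bh_select(p, q = q)
  nm <- colnames(x) %||% names(load1)
  cls <- if (!is.null(classes)) {
    classes$class[match(nm, classes$name)]
  } else NA_character_
  out <- data.frame(
    metabolite = nm, class = cls, loading = unname(load1),
    tau = unname(kt[1L, ]), p_value = unname(p),
    neg_log10_p = -log10(unname(p)),
    significant = bh$significant,
    stringsAsFactors = FALSE
  )
  attr(out, "bh") <- bh
  out
}

#' 3D-volcano coordinates from an importance table
#'
#' One row per metabolite: x = loading on the first joint component,
#' y = Kendall tau, z = -log10 p, plus the class color key and the
#' significance flag (only significant metabolites are colored in the
#' reference display convention).
#'
#' @param records output of [importance_table()].
#' @return data frame with columns `metabolite`, `class`, `x_loading`,
#'   `y_tau`, `z_neg_log10_p`, `significant`, `color`.
#' @export
volcano_coordinates <- function(records) {
  stopifnot(all(c("metabolite", "loading", "tau", "p_value") %in%
                  names(records)))
  data.frame(
    metabolite = records$metabolite,
    class = records$class,
    x_loading = records$loading,
    y_tau = records$tau,
    z_neg_log10_p = -log10(records$p_value),
    significant = records$significant,
    color = ifelse(records$significant,
                   unname(VOLCANO_COLORS[records$class]), "grey"),
    stringsAsFactors = FALSE
  )
}
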