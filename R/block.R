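# ConcentrationBlock: one samples x metabolites concentration matrix with
# sample metadata and a validity (dynamic-range) mask.

GROUP_LEVELS <- c("SHAM", "HCD", "ANG")

# Cells carrying any of these strings (or empty) are treated as outside the
# dynamic range; targeted-panel exports vary in how they flag censored values.
LOD_SENTINELS <- c("<LOD", "< LOD", "NA", "")

#' Construct a concentration block
#'
#' @param values numeric matrix, samples in rows, metabolites in columns
#'   (concentrations in uM, or uM/mg after tissue-weight normalization).
#' @param samples data frame with columns `sample_id`, `group` (levels
#'   SHAM/HCD/ANG) and, for aorta blocks, positive `aorta_weight_mg`.
#' @param metabolites descriptor data frame as from
#'   [parse_metabolite_names()]; defaults to parsing `colnames(values)`.
#' @param valid_mask logical matrix, `TRUE` where the measurement lies in
#'   the dynamic range; defaults to all-valid.
#' @param tissue `"plasma"` or `"aorta"`.
#' @param units concentration units label.
#' @return object of class `conc_block`.
#' @export
conc_block <- function(values, samples, metabolites = NULL,
                       valid_mask = NULL, tissue = c("plasma", "aorta"),
                       units = "uM") {
  tissue <- match.arg(tissue)
  values <- as.matrix(values)
  if (is.null(metabolites)) {
    metabolites <- parse_metabolite_names(colnames(values))
  }
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, nrow(values), ncol(values))
  }
  stopifnot(
    nrow(values) == nrow(samples),
    ncol(values) == nrow(metabolites),
    identical(dim(valid_mask), dim(values)),
    is.logical(valid_mask),
    all(c("sample_id", "group") %in% names(samples))
  )
  if (anyDuplicated(metabolites$name)) stop("duplicate metabolite names")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (!all(as.character(samples$group) %in% GROUP_LEVELS)) {
    stop("group labels must be one of ", paste(GROUP_LEVELS, collapse = "/"))
  }
  samples$group <- factor(as.character(samples$group), levels = GROUP_LEVELS)
  if (tissue == "aorta") {
    w <- samples$aorta_weight_mg
    if (is.null(w) || anyNA(w) || any(w <= 0)) {
      stop("aorta blocks require positive aorta_weight_mg for every sample")
    }
  }
  if (any(!is.finite(values[valid_mask]))) {
    stop("non-finite concentration inside the dynamic range")
  }
  dimnames(values) <- list(samples$sample_id, metabolites$name)
  dimnames(valid_mask) <- dimnames(values)
  structure(
    list(values = values, valid_mask = valid_mask, samples = samples,
         metabolites = metabolites, tissue = tissue, units = units),
    class = "conc_block"
  )
}

#' @export
print.conc_block <- function(x, ...) {
  cat(sprintf(
    "<conc_block> %s: %d samples x %d metabolites [%s], %.1f%% in range\n",
    x$tissue, nrow(x$values), ncol(x$values), x$units,
    100 * mean(x$valid_mask)
  ))
  print(table(x$samples$group))
  invisible(x)
}

#' @export
dim.conc_block <- function(x) dim(x$values)

#' Read a concentration block from a delimited text export
#'
#' Expects a wide table (CSV or TSV, sniffed from the first line): metadata
#' columns `sample_id`, `group`, optionally `tissue` and `aorta_weight_mg`,
#' followed by one column per metabolite. Cells may hold a number or a
#' below-LOD sentinel (`<LOD`, `< LOD`, `NA`, empty), which is recorded as
#' outside the dynamic range.
#'
#' @param path file path.
#' @param tissue `"plasma"` or `"aorta"`; aorta requires weights.
#' @return a [conc_block()].
#' @export
read_block <- function(path, tissue = c("plasma", "aorta")) {
  tissue <- match.arg(tissue)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"",
                           fileEncoding = "UTF-8")
  meta_cols <- intersect(c("sample_id", "group", "tissue",
                           "aorta_weight_mg"), names(raw))
  if (!all(c("sample_id", "group") %in% meta_cols)) {
    stop("missing metadata column(s): ",
         paste(setdiff(c("sample_id", "group"), meta_cols), collapse = ", "))
  }
  met_cols <- setdiff(names(raw), meta_cols)
  if (length(met_cols) == 0L) stop("no metabolite columns found")
  if (anyDuplicated(met_cols)) stop("duplicate metabolite names in header")

  cells <- as.matrix(raw[, met_cols, drop = FALSE])
  cells_trim <- trimws(cells)
  mask <- !(cells_trim %in% LOD_SENTINELS)
  dim(mask) <- dim(cells)
  vals <- suppressWarnings(as.numeric(cells_trim))
  dim(vals) <- dim(cells)
  bad <- mask & is.na(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' (sample %s, metabolite %s)",
                 cells[bad][1], raw$sample_id[idx[1]], met_cols[idx[2]]))
  }
  vals[!mask] <- NA_real_

  samples <- data.frame(sample_id = raw$sample_id, group = raw$group,
                        stringsAsFactors = FALSE)
  if ("aorta_weight_mg" %in% names(raw)) {
    samples$aorta_weight_mg <- as.numeric(raw$aorta_weight_mg)
  } else if (tissue == "aorta") {
    stop("aorta tissue requires an aorta_weight_mg column")
  }
  vals[!mask] <- 0  # placeholder under the mask; never read while invalid
  conc_block(vals, samples, parse_metabolite_names(met_cols),
             mask, tissue = tissue)
}

#' Write a concentration block as delimited text
#'
#' Inverse of [read_block()]: out-of-range cells are written as `<LOD`.
#'
#' @param block a [conc_block()].
#' @param path output path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_block <- function(block, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  cells <- matrix(
    vapply(block$values, function(v) format(v, digits = 17), ""),
    nrow = nrow(block$values)
  )
  cells[!block$valid_mask] <- "<LOD"
  out <- data.frame(sample_id = block$samples$sample_id,
                    group = as.character(block$samples$group),
                    tissue = block$tissue,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(block$samples$aorta_weight_mg)) {
    out$aorta_weight_mg <- format(block$samples$aorta_weight_mg, digits = 17)
  }
  out <- cbind(out, as.data.frame(cells, stringsAsFactors = FALSE))
  names(out)[(ncol(out) - ncol(cells) + 1):ncol(out)] <- block$metabolites$name
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
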