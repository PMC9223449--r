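# Metabolite panel taxonomy: analyte classes and acyl-chain annotation for a
# Biocrates p180-style targeted panel (40 acylcarnitines, 21 amino acids,
# 21 biogenic amines, 76 phosphatidylcholines, 14 lysophosphatidylcholines,
# 15 sphingomyelins, hexoses).

METABOLITE_CLASSES <- c(
  "acylcarnitine", "aminoacid", "biogenic_amine", "phosphatidylcholine",
  "lysophosphatidylcholine", "sphingomyelin", "hexose"
)

LIPID_LIKE_CLASSES <- c(
  "acylcarnitine", "phosphatidylcholine", "lysophosphatidylcholine",
  "sphingomyelin"
)

.P180_AMINO_ACIDS <- c(
  "Ala", "Arg", "Asn", "Asp", "Cit", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Orn", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr",
  "Val"
)

.P180_BIOGENIC_AMINES <- c(
  "Ac-Orn", "ADMA", "alpha-AAA", "Carnosine", "Creatinine", "DOPA",
  "Dopamine", "Histamine", "Kynurenine", "Met-SO", "Nitro-Tyr", "PEA",
  "Putrescine", "Sarcosine", "SDMA", "Serotonin", "Spermidine", "Spermine",
  "t4-OH-Pro", "Taurine", "total DMA"
)

#' Parse a metabolite name into its panel descriptor
#'
#' Names follow the targeted-panel grammar: acylcarnitines are `"C X:Y"`
#' (with optional `-OH` / `-DC` modifier suffixes and `"C0"` for free
#' carnitine), phosphatidylcholines `"PC aa C X:Y"` or `"PC ae C X:Y"`,
#' lysophosphatidylcholines `"lysoPC a C X:Y"`, sphingomyelins
#' `"SM C X:Y"` or `"SM (OH) C X:Y"`, hexoses `"H1"`; everything else is an
#' amino acid or a biogenic amine, resolved against the panel's fixed
#' name lists. `X` is the acyl-chain carbon count, `Y` the number of
#' double bonds (`Y` absent means 0).
#'
#' @param names character vector of analyte names.
#' @return data frame with columns `name`, `class`, `acyl_carbons`,
#'   `acyl_double_bonds`; the acyl columns are `NA` for non-lipid classes.
#' @examples
#' parse_metabolite_names(c("PC aa C36:2", "lysoPC a C18:1", "C0", "Gly"))
#' @export
parse_metabolite_names <- function(names) {
  stopifnot(is.character(names), !anyNA(names))
  if (anyDuplicated(names)) {
    stop("duplicate metabolite names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  n <- length(names)
  class <- character(n)
  carbons <- rep(NA_integer_, n)
  dbl <- rep(NA_integer_, n)

  chain <- function(x) {
    # x like "C36:2" or "C0"; returns c(carbons, double_bonds)
    m <- regmatches(x, regexec("^C([0-9]+)(:([0-9]+))?$", x))[[1]]
    c(as.integer(m[2]), ifelse(m[4] == "", 0L, as.integer(m[4])))
  }

  for (i in seq_len(n)) {
    nm <- names[i]
    if (grepl("^PC (aa|ae) C[0-9]+:[0-9]+$", nm)) {
      class[i] <- "phosphatidylcholine"
      cd <- chain(sub("^PC (aa|ae) ", "", nm))
    } else if (grepl("^lysoPC a C[0-9]+:[0-9]+$", nm)) {
      class[i] <- "lysophosphatidylcholine"
      cd <- chain(sub("^lysoPC a ", "", nm))
    } else if (grepl("^SM( \\(OH\\))? C[0-9]+:[0-9]+$", nm)) {
      class[i] <- "sphingomyelin"
      cd <- chain(sub("^SM( \\(OH\\))? ", "", nm))
    } else if (grepl("^C[0-9]+(:[0-9]+)?(-[-A-Za-z]+)?$", nm)) {
      class[i] <- "acylcarnitine"
      cd <- chain(sub("(-[-A-Za-z]+)?$", "", nm))
    } else if (grepl("^H[0-9]+$", nm)) {
      class[i] <- "hexose"
      cd <- c(NA_integer_, NA_integer_)
    } else if (nm %in% .P180_AMINO_ACIDS) {
      class[i] <- "aminoacid"
      cd <- c(NA_integer_, NA_integer_)
    } else if (nm %in% .P180_BIOGENIC_AMINES) {
      class[i] <- "biogenic_amine"
      cd <- c(NA_integer_, NA_integer_)
    } else {
      stop("unrecognized metabolite name: '", nm, "'")
    }
    carbons[i] <- cd[1]
    dbl[i] <- cd[2]
  }
  data.frame(
    name = names, class = class,
    acyl_carbons = carbons, acyl_double_bonds = dbl,
    stringsAsFactors = FALSE
  )
}

#' Default p180-style metabolite panel
#'
#' A 188-analyte layout mirroring the composition of the Biocrates
#' AbsoluteIDQ p180 kit: 40 acylcarnitines, 21 amino acids, 21 biogenic
#' amines, 76 phosphatidylcholines (38 diacyl `aa` + 38 acyl-alkyl `ae`),
#' 14 lysophosphatidylcholines, 15 sphingomyelins, and the hexose sum
#' (`H1`).
#'
#' @return data frame as produced by [parse_metabolite_names()].
#' @export
default_panel <- function() {
  ac <- c(
    "C0", "C2", "C3", "C3:1", "C3-OH", "C4", "C4:1", "C4-OH",
    "C5", "C5:1", "C5:1-DC", "C5-DC", "C5-M-DC", "C5-OH",
    "C6", "C6:1", "C7-DC", "C8", "C9",
    "C10", "C10:1", "C10:2", "C12", "C12:1", "C12-DC",
    "C14", "C14:1", "C14:1-OH", "C14:2", "C14:2-OH",
    "C16", "C16:1", "C16:1-OH", "C16:2", "C16:2-OH", "C16-OH",
    "C18", "C18:1", "C18:1-OH", "C18:2"
  )
  pc_aa <- paste0("PC aa C", c(
    "24:0", "26:0", "28:1", "30:0", "30:2", "32:0", "32:1", "32:2",
    "32:3", "34:1", "34:2", "34:3", "34:4", "36:0", "36:1", "36:2",
    "36:3", "36:4", "36:5", "36:6", "38:0", "38:1", "38:3", "38:4",
    "38:5", "38:6", "40:1", "40:2", "40:3", "40:4", "40:5", "40:6",
    "42:0", "42:1", "42:2", "42:4", "42:5", "42:6"
  ))
  pc_ae <- paste0("PC ae C", c(
    "30:0", "30:1", "30:2", "32:1", "32:2", "34:0", "34:1", "34:2",
    "34:3", "36:0", "36:1", "36:2", "36:3", "36:4", "36:5", "38:0",
    "38:1", "38:2", "38:3", "38:4", "38:5", "38:6", "40:1", "40:2",
    "40:3", "40:4", "40:5", "40:6", "42:0", "42:1", "42:2", "42:3",
    "42:4", "42:5", "44:3", "44:4", "44:5", "44:6"
  ))
  lpc <- paste0("lysoPC a C", c(
    "14:0", "16:0", "16:1", "17:0", "18:0", "18:1", "18:2", "20:3",
    "20:4", "24:0", "26:0", "26:1", "28:0", "28:1"
  ))
  sm <- c(
    paste0("SM (OH) C", c("14:1", "16:1", "22:1", "22:2", "24:1")),
    paste0("SM C", c("16:0", "16:1", "18:0", "18:1", "20:2", "22:3",
                     "24:0", "24:1", "26:0", "26:1"))
  )
  nm <- c(ac, .P180_AMINO_ACIDS, .P180_BIOGENIC_AMINES, pc_aa, pc_ae,
          lpc, sm, "H1")
  stopifnot(length(nm) == 188L)
  parse_metabolite_names(nm)
}
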