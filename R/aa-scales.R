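# Per-residue scales used across the package: hydrophobicity (transfer free
# energies) and formal charge. All sequences are restricted to the 20
# canonical one-letter codes; anything else is rejected up front.

AA_CANONICAL <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Apparent free energy of membrane insertion via the Sec translocon
# (kcal/mol; negative = favours the bilayer). The "biological" scale.
SCALE_BIOLOGICAL <- c(
  A = 0.11, R = 2.58, N = 2.05, D = 3.49, C = -0.13,
  Q = 2.36, E = 2.68, G = 0.74, H = 2.06, I = -0.60,
  L = -0.55, K = 2.71, M = -0.10, F = -0.32, P = 2.23,
  S = 0.84, T = 0.52, W = 0.30, Y = 0.68, V = -0.31
)

# Kyte-Doolittle hydropathy (unitless; positive = hydrophobic).
SCALE_KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

AA_CHARGE <- c(
  A = 0L, R = 1L, N = 0L, D = -1L, C = 0L,
  Q = 0L, E = -1L, G = 0L, H = 0L, I = 0L,
  L = 0L, K = 1L, M = 0L, F = 0L, P = 0L,
  S = 0L, T = 0L, W = 0L, Y = 0L, V = 0L
)

#' Available hydrophobicity scales
#'
#' Per-residue hydrophobicity scales known to the package. `"biological"` is
#' the translocon-based apparent free energy of membrane insertion
#' (kcal/mol, negative values favour the bilayer) and is the package default;
#' `"kyte_doolittle"` is the classic hydropathy index (positive =
#' hydrophobic).
#'
#' @return A named list of named numeric vectors (one value per canonical
#'   amino acid).
#' @export
#' @examples
#' names(hydrophobicity_scales())
#' hydrophobicity_scales()$biological["L"]
hydrophobicity_scales <- function() {
  list(
    biological = SCALE_BIOLOGICAL,
    kyte_doolittle = SCALE_KYTE_DOOLITTLE
  )
}

get_scale <- function(scale_name) {
  scales <- hydrophobicity_scales()
  if (!scale_name %in% names(scales)) {
    abort(paste0(
      "Unknown hydrophobicity scale '", scale_name, "'. Available scales: ",
      paste(names(scales), collapse = ", ")
    ))
  }
  scales[[scale_name]]
}

# Split a sequence string into residues, validating the alphabet.
aa_chars <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq)) {
    abort(paste0(what, " must be a single character string"))
  }
  if (nchar(seq) == 0L) {
    abort(paste0(what, " must be non-empty"))
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), AA_CANONICAL)
  if (length(bad) > 0L) {
    abort(paste0(
      what, " contains non-canonical residue(s): ",
      paste(bad, collapse = ", "),
      " (only the 20 canonical one-letter codes are accepted)"
    ))
  }
  ch
}
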