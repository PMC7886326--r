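# Construct bookkeeping for force-profile analysis (FPA). An FPA series
# places a force-generating element (e.g. a TMH) at increasing distance from
# a translational arrest peptide (AP). N counts residues from the start of
# the protein through the last AP residue; the chain synthesized at the
# arrest point therefore has exactly N residues, and the C-terminal tail is
# only made once the arrest is released.

#' Built-in arrest peptides
#'
#' The three SecM-derived arrest peptides used throughout the package, in
#' increasing stalling strength: the 17-residue E. coli SecM AP
#' (`SecM-Ec`), the medium-strong `SecM-Ec-Ms` variant and the strong
#' suppressor-derived `SecM-Ec-Sup1` variant.
#'
#' @return A tibble with columns `name`, `sequence`, `strength_class`.
#' @export
#' @examples
#' arrest_peptides()
arrest_peptides <- function() {
  tibble(
    name = c("SecM-Ec", "SecM-Ec-Ms", "SecM-Ec-Sup1"),
    sequence = c("FSTPVWISQAQGIRAGP", "FSTPVWISQHAPIRGSP", "FSTPVWISQAPPIRAGP"),
    strength_class = factor(c("weak", "medium", "strong"),
      levels = c("weak", "medium", "strong"), ordered = TRUE
    )
  )
}

#' Create (or look up) an arrest peptide
#'
#' With only `name`, returns the built-in AP of that name (see
#' [arrest_peptides()]). With `sequence` and `strength_class`, constructs a
#' custom AP after validating the alphabet.
#'
#' @param name AP identifier.
#' @param sequence Amino-acid sequence (canonical one-letter codes), or
#'   `NULL` to look up a built-in.
#' @param strength_class One of `"weak"`, `"medium"`, `"strong"`.
#' @return An object of class `arrest_peptide`: a list with fields `name`,
#'   `sequence`, `strength_class`.
#' @export
#' @examples
#' arrest_peptide("SecM-Ec")
#' arrest_peptide("custom", "FSTPVWISQAQGIRAGP", "weak")
arrest_peptide <- function(name, sequence = NULL, strength_class = NULL) {
  if (is.null(sequence)) {
    builtin <- arrest_peptides()
    hit <- builtin[builtin$name == name, ]
    if (nrow(hit) == 0L) {
      abort(paste0(
        "Unknown built-in arrest peptide '", name, "'. Built-ins: ",
        paste(builtin$name, collapse = ", ")
      ))
    }
    sequence <- hit$sequence
    strength_class <- as.character(hit$strength_class)
  }
  strength_class <- match.arg(strength_class, c("weak", "medium", "strong"))
  aa_chars(sequence, "arrest-peptide sequence")
  structure(
    list(name = name, sequence = sequence, strength_class = strength_class),
    class = "arrest_peptide"
  )
}

#' @export
print.arrest_peptide <- function(x, ...) {
  cat("<arrest_peptide> ", x$name, " (", x$strength_class, "): ",
    x$sequence, "\n",
    sep = ""
  )
  invisible(x)
}

as_arrest_peptide <- function(ap) {
  if (inherits(ap, "arrest_peptide")) {
    return(ap)
  }
  if (is.character(ap) && length(ap) == 1L) {
    return(arrest_peptide(ap))
  }
  abort("`ap` must be an arrest_peptide or the name of a built-in one")
}

#' Build an FPA truncation series
#'
#' Generates the construct series of an FPA experiment: for each requested
#' `N` (residues from the protein start through the last AP residue) the
#' protein + linker block is truncated from its C-terminal end so that
#' `nchar(prefix) + nchar(ap$sequence) == N`, with the tag + AP block held
#' constant across the series. Truncation removes residues from the end of
#' the linker first and only then from the protein C-terminus
#' (`truncate = "linker_first"`), or from the protein first
#' (`truncate = "protein_first"`).
#'
#' @param protein_seq Target protein sequence.
#' @param linker_seq Linker sequence (may be `""`).
#' @param tag_seq Epitope-tag sequence immediately before the AP (may be
#'   `""`); part of the constant block, never truncated.
#' @param ap An [arrest_peptide()] (or built-in AP name).
#' @param tail_seq C-terminal tail translated after arrest release.
#' @param n_values Integer vector of N values.
#' @param truncate Truncation order, `"linker_first"` (default) or
#'   `"protein_first"`.
#' @param id_prefix Construct-id prefix; ids are `<prefix>_N<N>`.
#' @return A tibble with one row per construct: `construct_id`, `N`,
#'   `prefix_seq`, `ap_name`, `ap_seq`, `tail_seq`, `arrest_seq` (the
#'   N-residue chain present at the arrest point) and `full_seq`
#'   (`arrest_seq` plus tail).
#' @export
#' @examples
#' ap <- arrest_peptide("SecM-Ec")
#' ser <- build_truncation_series(
#'   strrep("A", 110), strrep("G", 34), strrep("S", 9), ap, strrep("T", 23),
#'   n_values = c(100, 105, 110)
#' )
#' ser[, c("construct_id", "N")]
build_truncation_series <- function(protein_seq, linker_seq, tag_seq, ap,
                                    tail_seq, n_values,
                                    truncate = c("linker_first", "protein_first"),
                                    id_prefix = "construct") {
  truncate <- match.arg(truncate)
  ap <- as_arrest_peptide(ap)
  protein <- aa_chars(protein_seq, "protein sequence")
  linker <- if (nzchar(linker_seq)) aa_chars(linker_seq, "linker sequence") else character(0)
  tag <- if (nzchar(tag_seq)) aa_chars(tag_seq, "tag sequence") else character(0)
  if (nzchar(tail_seq)) aa_chars(tail_seq, "tail sequence")
  ap_len <- nchar(ap$sequence)
  n_min <- ap_len + length(tag)
  n_values <- as.integer(n_values)
  if (any(n_values < n_min)) {
    abort(paste0(
      "N values ", paste(n_values[n_values < n_min], collapse = ", "),
      " are too small to fit the tag + AP block; minimum N is ", n_min
    ))
  }
  n_max <- length(protein) + length(linker) + n_min
  if (any(n_values > n_max)) {
    abort(paste0(
      "N values ", paste(n_values[n_values > n_max], collapse = ", "),
      " exceed the full construct (maximum N is ", n_max, ")"
    ))
  }

  body_for <- function(keep) {
    # keep = residues of protein + linker retained ahead of the tag
    if (truncate == "linker_first") {
      paste(c(protein, linker)[seq_len(keep)], collapse = "")
    } else {
      nl <- length(linker)
      if (keep >= nl) {
        paste(c(protein[seq_len(keep - nl)], linker), collapse = "")
      } else {
        paste(linker[seq_len(keep)], collapse = "")
      }
    }
  }

  rows <- purrr::map(n_values, function(N) {
    keep <- N - ap_len - length(tag)
    prefix <- paste0(body_for(keep), paste(tag, collapse = ""))
    arrest_seq <- paste0(prefix, ap$sequence)
    tibble(
      construct_id = paste0(id_prefix, "_N", N),
      N = N,
      prefix_seq = prefix,
      ap_name = ap$name,
      ap_seq = ap$sequence,
      tail_seq = tail_seq,
      arrest_seq = arrest_seq,
      full_seq = paste0(arrest_seq, tail_seq)
    )
  })
  dplyr::bind_rows(rows) %>% arrange(.data$N)
}

#' Distance of a residue from the peptidyl-transferase center
#'
#' For a construct of length `N` (residues from the protein start through
#' the last AP residue), the residue at 1-based position `residue_index` lies
#' `N - residue_index` residues from the ribosomal peptidyl-transferase
#' center (PTC); the last AP residue is at distance 0. Each residue
#' corresponds to roughly 3 Angstrom of extended nascent chain, so the
#' physical distance is about `3 * (N - residue_index)` Angstrom (see
#' [residues_to_angstrom()]).
#'
#' @param n Construct length N (vectorized).
#' @param residue_index 1-based residue position (vectorized).
#' @return Integer vector of distances in residues.
#' @export
#' @examples
#' ptc_distance(200, 155) # middle of GlpG TMH2 at N_max of peak III
ptc_distance <- function(n, residue_index) {
  n <- as.integer(n)
  residue_index <- as.integer(residue_index)
  if (any(n < 1L) || any(residue_index < 1L)) {
    abort("`n` and `residue_index` must be positive integers")
  }
  if (any(residue_index > n)) {
    abort("`residue_index` exceeds `n`: that residue has not been synthesized yet")
  }
  n - residue_index
}

#' Convert a PTC distance in residues to an approximate Angstrom scale
#'
#' Uses the ~3 Angstrom-per-residue extension of a nascent chain in the
#' ribosomal exit tunnel. An estimate, not a measurement.
#'
#' @param d Distance in residues.
#' @param angstrom_per_residue Conversion factor (default 3).
#' @return Numeric vector of Angstrom estimates.
#' @export
residues_to_angstrom <- function(d, angstrom_per_residue = 3) {
  d * angstrom_per_residue
}

#' Sequence window anchored at a given PTC offset
#'
#' Extracts from the arrested chain (length `N`) the `width`-residue window
#' whose first residue lies `offset` residues from the PTC. Supports
#' building the anchored alignments used to compare peak sequences across
#' constructs (e.g. aligning all peaks from their N_start values and marking
#' the 45-residue position).
#'
#' @param construct Either a one-row data frame with columns `arrest_seq`
#'   (or `full_seq`) and `N`, or a list/row with those fields.
#' @param offset PTC offset (residues) of the window's anchor (first)
#'   residue; 0 is the last AP residue.
#' @param width Window width in residues.
#' @return A one-row tibble: `window_seq`, `anchor_index`, `truncated`
#'   (TRUE if the requested window ran past either chain end and was
#'   clipped).
#' @export
#' @examples
#' ser <- build_truncation_series(
#'   strrep("A", 60), "", strrep("S", 9), arrest_peptide("SecM-Ec"),
#'   "", n_values = 50
#' )
#' window_at_ptc_offset(ser[1, ], offset = 45, width = 1) # residue 5
window_at_ptc_offset <- function(construct, offset, width) {
  if (is.data.frame(construct)) {
    if (nrow(construct) != 1L) abort("`construct` must be a single row")
    construct <- as.list(construct)
  }
  chain <- construct$arrest_seq
  if (is.null(chain)) {
    if (is.null(construct$full_seq) || is.null(construct$N)) {
      abort("`construct` must carry `arrest_seq` (or `full_seq`) and `N`")
    }
    chain <- substr(construct$full_seq, 1L, construct$N)
  }
  N <- as.integer(construct$N)
  if (nchar(chain) < N) abort("chain shorter than N; inconsistent construct")
  chain <- substr(chain, 1L, N)
  if (width < 1L) abort("`width` must be >= 1")
  anchor <- N - as.integer(offset)
  if (anchor < 1L || anchor > N) {
    abort(paste0(
      "window anchor (offset ", offset, " from the PTC) lies outside the ",
      "synthesized chain of length ", N
    ))
  }
  stop_at <- anchor + as.integer(width) - 1L
  truncated <- stop_at > N
  window <- substr(chain, anchor, min(stop_at, N))
  if (truncated) {
    warn("window extends past the PTC end of the chain; clipped")
  }
  tibble(window_seq = window, anchor_index = anchor, truncated = truncated)
}

#' Read / write FASTA files of amino-acid sequences
#'
#' Thin wrappers around Biostrings with canonical-alphabet validation:
#' `read_fasta()` returns a tibble of records, `write_fasta()` writes one.
#'
#' @param path File path.
#' @param records A data frame with columns `id` and `seq`.
#' @param width Line-wrap width for writing.
#' @return `read_fasta()`: a tibble with columns `id`, `seq` (empty for an
#'   empty file). `write_fasta()`: the path, invisibly.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("read_fasta() requires the Biostrings package")
  }
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (file.size(path) == 0L) {
    return(tibble(id = character(0), seq = character(0)))
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort(paste0("Malformed FASTA file ", path, ": ", conditionMessage(e)))
  )
  out <- tibble(
    id = sub("\\s.*$", "", names(set)),
    seq = unname(as.character(set))
  )
  purrr::walk2(out$seq, out$id, function(s, id) {
    aa_chars(s, paste0("sequence of record '", id, "'"))
  })
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  purrr::walk2(records$seq, records$id, function(s, id) {
    aa_chars(s, paste0("sequence of record '", id, "'"))
  })
  lines <- purrr::map2(records$id, records$seq, function(id, s) {
    body <- substring(
      s, seq(1L, nchar(s), by = width),
      pmin(seq(width, nchar(s) + width - 1L, by = width), nchar(s))
    )
    c(paste0(">", id), body)
  })
  writeLines(unlist(lines), path)
  invisible(path)
}
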