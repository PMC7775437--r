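#' Define a bisulfite amplicon
#'
#' An amplicon spec is the coordinate frame for everything downstream: it
#' holds the original (unconverted, top-strand) reference sequence, the
#' 1-based positions of the C of every CpG dinucleotide to be called, and
#' the per-read QC thresholds used when calling bisulfite reads against it.
#'
#' @param name Amplicon identifier, e.g. `"Hsf4"`.
#' @param reference_seq Uppercase DNA string: the genomic top strand
#'   *before* bisulfite conversion.
#' @param cpg_positions Strictly increasing integer vector of 1-based
#'   offsets of the C of each CG dinucleotide in `reference_seq`.
#' @param max_mismatch_frac Maximum tolerated fraction of mismatches at
#'   comparable non-C reference positions before a read fails QC.
#'   Default 0.1.
#' @param min_conversion Minimum bisulfite conversion rate (fraction of
#'   non-CpG reference Cs read as T) for a read to pass QC. Default 0.9.
#'
#' @return An object of class `amplicon_spec`.
#' @examples
#' amp <- amplicon("toy", "ACGTCGA", c(2, 5))
#' amp$cpg_positions
#' @export
amplicon <- function(name, reference_seq, cpg_positions,
                     max_mismatch_frac = 0.1, min_conversion = 0.9) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  reference_seq <- toupper(as.character(reference_seq))
  if (grepl("[^ACGT]", reference_seq)) {
    abort("`reference_seq` may only contain A, C, G, T.")
  }
  cpg_positions <- as.integer(cpg_positions)
  if (length(cpg_positions) == 0L) abort("At least one CpG position is required.")
  if (is.unsorted(cpg_positions, strictly = TRUE)) {
    abort("`cpg_positions` must be strictly increasing.")
  }
  if (min(cpg_positions) < 1L ||
      max(cpg_positions) + 1L > nchar(reference_seq)) {
    abort("`cpg_positions` out of range for `reference_seq`.")
  }
  ref_chars <- strsplit(reference_seq, "", fixed = TRUE)[[1L]]
  if (!all(ref_chars[cpg_positions] == "C" &
           ref_chars[cpg_positions + 1L] == "G")) {
    abort("Every CpG position must point at the C of a CG dinucleotide.")
  }
  stopifnot_scalar_fraction(max_mismatch_frac, "max_mismatch_frac")
  stopifnot_scalar_fraction(min_conversion, "min_conversion")
  structure(
    list(
      name = name,
      reference_seq = reference_seq,
      cpg_positions = cpg_positions,
      max_mismatch_frac = max_mismatch_frac,
      min_conversion = min_conversion
    ),
    class = "amplicon_spec"
  )
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat(sprintf("<amplicon_spec> %s: %d bp, %d CpGs (QC: mismatch <= %.2f, conversion >= %.2f)\n",
              x$name, nchar(x$reference_seq), length(x$cpg_positions),
              x$max_mismatch_frac, x$min_conversion))
  invisible(x)
}

#' @export
format.amplicon_spec <- function(x, ...) {
  sprintf("%s (%d CpGs)", x$name, length(x$cpg_positions))
}

# deterministic synthetic reference: CpGs separated by spacer units drawn
# from a fixed cycle; units contain non-CpG Cs (for conversion-rate QC)
# and are chosen so that no accidental CG dinucleotide can arise, at unit
# junctions or around the inserted CpGs
make_reference <- function(n_cpgs, units_per_gap = 3L) {
  units <- c("TACA", "CTGA", "ATCA", "TGCT", "ACTT")
  k <- 0L
  next_units <- function(n) {
    out <- units[(k + seq_len(n) - 1L) %% length(units) + 1L]
    k <<- k + n
    paste0(out, collapse = "")
  }
  parts <- character(0)
  positions <- integer(0)
  at <- 0L
  for (i in seq_len(n_cpgs)) {
    sp <- next_units(units_per_gap)
    parts <- c(parts, sp, "CG")
    at <- at + nchar(sp)
    positions <- c(positions, at + 1L)
    at <- at + 2L
  }
  tail <- next_units(units_per_gap)
  list(sequence = paste0(c(parts, tail), collapse = ""),
       cpg_positions = positions)
}

#' Default three-amplicon panel (Prima1, Hsf4, Kcns1)
#'
#' The murine targeted clocks used throughout this package are built on
#' three age-associated regions in *Prima1*, *Hsf4* and *Kcns1*, covering
#' 4, 12 and 21 neighboring CpGs respectively. The reference sequences
#' shipped here are **synthetic stand-ins** with those CpG counts and
#' realistic spacing -- generated deterministically, not the genomic
#' sequences -- so the package is self-contained; supply your own
#' [amplicon()] specs to work with real amplicons.
#'
#' @param max_mismatch_frac,min_conversion QC thresholds passed to
#'   [amplicon()].
#' @return Named list of three `amplicon_spec` objects.
#' @examples
#' lengths(purrr::map(default_panel(), "cpg_positions"))
#' @export
default_panel <- function(max_mismatch_frac = 0.1, min_conversion = 0.9) {
  n_cpgs <- c(Prima1 = 4L, Hsf4 = 12L, Kcns1 = 21L)
  purrr::imap(as.list(n_cpgs), function(n, nm) {
    ref <- make_reference(n)
    amplicon(nm, ref$sequence, ref$cpg_positions,
             max_mismatch_frac = max_mismatch_frac,
             min_conversion = min_conversion)
  })
}

# CpG ids in "amplicon:index" form (index is the rank of the CpG within
# the amplicon, 1-based, 5'->3')
cpg_ids <- function(spec) {
  paste0(spec$name, ":", seq_along(spec$cpg_positions))
}
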