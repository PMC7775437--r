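#' Call per-read binary CpG methylation against an amplicon reference
#'
#' Bisulfite conversion leaves methylated cytosines as C and converts
#' unmethylated cytosines to T (read as T after PCR). Amplicon reads are
#' fixed-layout products anchored at the reference start, so calling is
#' positional: no indel alignment is attempted, and gross failures are
#' caught by the mismatch-fraction QC instead. At each CpG cytosine an
#' observed C is called methylated, T unmethylated, anything else (other
#' bases, or positions past the read end) missing. Two per-read QC
#' statistics are computed: the bisulfite conversion rate (fraction of
#' non-CpG reference cytosines read as T) and the mismatch fraction over
#' comparable positions where the reference is not a C (C positions differ
#' legitimately after conversion).
#'
#' Reads from the bottom strand live in G-to-A space; with
#' `orient = "auto"` each read is additionally evaluated after
#' reverse-complementing into top-strand coordinates (where the CpG call
#' sits on the G of the dinucleotide: G methylated, A unmethylated) and
#' the orientation with the lower mismatch fraction wins, ties going to
#' the forward interpretation.
#'
#' @param reads Character vector of read sequences (5'->3').
#' @param spec An [amplicon()] specification.
#' @param orient `"auto"` (default) tries forward and reverse-complement
#'   interpretations per read; `"forward"` assumes top-strand reads.
#' @return A tibble with one row per read: `pattern` (string over
#'   `0`/`1`/`?`, one character per CpG in amplicon order),
#'   `conversion_rate`, `mismatch_frac`, `passed_qc`, `strand`.
#' @examples
#' amp <- amplicon("toy", "ACGTCGA", c(2, 5))
#' call_reads(c("ATGTCGA", "ACGTCGA"), amp, orient = "forward")
#' @export
call_reads <- function(reads, spec, orient = c("auto", "forward")) {
  stopifnot(inherits(spec, "amplicon_spec"))
  orient <- match.arg(orient)
  reads <- toupper(as.character(reads))
  n <- length(reads)
  if (n == 0L) {
    return(tibble::tibble(pattern = character(), conversion_rate = double(),
                          mismatch_frac = double(), passed_qc = logical(),
                          strand = character()))
  }
  # chunk so the per-chunk character matrix stays small
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 20000L))
  out <- purrr::map(chunks, function(idx) call_reads_chunk(reads[idx], spec, orient))
  dplyr::bind_rows(out)
}

#' Call a single read
#'
#' Convenience wrapper around [call_reads()] for one sequence.
#'
#' @inheritParams call_reads
#' @param read_seq A single read sequence.
#' @return A one-row tibble (see [call_reads()]).
#' @export
call_read <- function(read_seq, spec, orient = c("auto", "forward")) {
  call_reads(read_seq, spec, orient)
}

call_reads_chunk <- function(reads, spec, orient) {
  fwd <- call_strand(reads, spec, strand = "top")
  if (orient == "forward") {
    fwd$strand <- ifelse(is.na(fwd$mismatch_frac), NA_character_, "+")
    return(fwd)
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(ifelse(nchar(reads) == 0L, "A", reads))))
  rc[nchar(reads) == 0L] <- ""
  rev <- call_strand(rc, spec, strand = "bottom")
  use_rev <- !is.na(rev$mismatch_frac) &
    (is.na(fwd$mismatch_frac) | rev$mismatch_frac < fwd$mismatch_frac)
  out <- fwd
  out[use_rev, ] <- rev[use_rev, ]
  out$strand <- ifelse(is.na(out$mismatch_frac), NA_character_,
                       ifelse(use_rev, "-", "+"))
  out
}

# positional calling in top-strand coordinates. strand = "top": reads are
# top-strand products, methylation read as C/T at the CpG C; strand =
# "bottom": reads have been reverse-complemented into top coordinates, so
# they align to the reference *end*, methylation is read as G/A at the CpG
# G, conversion over non-CpG reference Gs, mismatches over non-G positions.
call_strand <- function(reads, spec, strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  ref <- strsplit(spec$reference_seq, "", fixed = TRUE)[[1L]]
  L <- length(ref)
  n <- length(reads)
  k <- length(spec$cpg_positions)

  empty <- nchar(reads) == 0L
  clipped <- substr(reads, 1L, L)
  if (strand == "top") {
    padded <- stringr::str_pad(clipped, L, side = "right", pad = "N")
  } else {
    padded <- stringr::str_pad(clipped, L, side = "left", pad = "N")
  }
  M <- matrix(unlist(strsplit(padded, "", fixed = TRUE), use.names = FALSE),
              nrow = n, ncol = L, byrow = TRUE)
  M[empty, ] <- "N"

  is_cpg_c <- rep(FALSE, L); is_cpg_c[spec$cpg_positions] <- TRUE
  is_cpg_g <- rep(FALSE, L); is_cpg_g[spec$cpg_positions + 1L] <- TRUE

  if (strand == "top") {
    call_pos <- spec$cpg_positions
    meth_base <- "C"; unmeth_base <- "T"
    conv_pos <- which(ref == "C" & !is_cpg_c)
    cmp_pos <- which(ref != "C")
  } else {
    call_pos <- spec$cpg_positions + 1L
    meth_base <- "G"; unmeth_base <- "A"
    conv_pos <- which(ref == "G" & !is_cpg_g)
    cmp_pos <- which(ref != "G")
  }

  calls <- M[, call_pos, drop = FALSE]
  pat <- matrix(NA_integer_, nrow = n, ncol = k)
  pat[calls == meth_base] <- 1L
  pat[calls == unmeth_base] <- 0L

  conv_obs <- M[, conv_pos, drop = FALSE]
  conv_seen <- conv_obs != "N"
  conv_n <- rowSums(conv_seen)
  conversion_rate <- ifelse(conv_n > 0,
                            rowSums(conv_obs == unmeth_base) / conv_n,
                            NA_real_)

  cmp_obs <- M[, cmp_pos, drop = FALSE]
  cmp_seen <- cmp_obs != "N"
  cmp_n <- rowSums(cmp_seen)
  cmp_ref <- matrix(ref[cmp_pos], nrow = n, ncol = length(cmp_pos), byrow = TRUE)
  mismatch_frac <- ifelse(cmp_n > 0,
                          rowSums(cmp_seen & cmp_obs != cmp_ref) / cmp_n,
                          NA_real_)

  covered_cpgs <- rowSums(!is.na(pat) | calls != "N")
  passed <- !empty &
    covered_cpgs > 0L &
    !is.na(mismatch_frac) & mismatch_frac <= spec$max_mismatch_frac &
    (is.na(conversion_rate) | conversion_rate >= spec$min_conversion)

  tibble::tibble(
    pattern = matrix_to_pattern(pat),
    conversion_rate = conversion_rate,
    mismatch_frac = mismatch_frac,
    passed_qc = passed,
    strand = NA_character_
  )
}

#' Tabulate binary methylation patterns from read calls
#'
#' Counts the distinct binary methylation patterns among QC-passing reads
#' of one amplicon in one sample: the single-read substrate for pattern
#' frequency heatmaps, neighbor correlations and single-read age
#' prediction. Patterns with missing calls are retained with `?`
#' characters; counts sum to the number of passing reads.
#'
#' @param calls Tibble from [call_reads()] (or any data frame with
#'   `pattern` and `passed_qc` columns, or `pattern` only, in which case
#'   all reads are taken as passing).
#' @param sample_id Sample identifier recorded in the table.
#' @param spec The [amplicon()] the reads were called against (supplies
#'   the amplicon name).
#' @return Tibble with columns `sample_id`, `amplicon`, `pattern`,
#'   `count`, sorted by decreasing count.
#' @export
pattern_table <- function(calls, sample_id, spec) {
  stopifnot(inherits(spec, "amplicon_spec"))
  calls <- tibble::as_tibble(calls)
  if (!"pattern" %in% names(calls)) abort("`calls` must have a `pattern` column.")
  if ("passed_qc" %in% names(calls)) {
    calls <- dplyr::filter(calls, .data$passed_qc)
  }
  if (nrow(calls) == 0L) {
    warn(sprintf("No QC-passing reads for sample '%s', amplicon '%s': empty pattern table.",
                 sample_id, spec$name))
    return(tibble::tibble(sample_id = character(), amplicon = character(),
                          pattern = character(), count = integer()))
  }
  calls |>
    dplyr::count(.data$pattern, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$pattern) |>
    dplyr::mutate(sample_id = sample_id, amplicon = spec$name,
                  .before = 1L)
}

#' Per-CpG methylation levels (beta values) from a pattern table
#'
#' Aggregates per-read binary calls to the per-CpG DNAm level: the
#' count-weighted fraction of methylated calls among non-missing calls at
#' each CpG. A CpG with no non-missing calls gets a missing beta.
#'
#' @param table A pattern table from [pattern_table()] (one sample, one
#'   amplicon).
#' @return Tibble with columns `sample_id`, `amplicon`, `cpg_index`,
#'   `beta` (fraction in \[0, 1\] or `NA`), `n_calls`.
#' @examples
#' tab <- tibble::tibble(sample_id = "s", amplicon = "a",
#'                       pattern = c("11", "00"), count = c(3L, 1L))
#' pattern_betas(tab)$beta  # 0.75 0.75
#' @export
pattern_betas <- function(table) {
  table <- tibble::as_tibble(table)
  if (nrow(table) == 0L) {
    warn("Empty pattern table: no betas to compute.")
    return(tibble::tibble(sample_id = character(), amplicon = character(),
                          cpg_index = integer(), beta = double(),
                          n_calls = integer()))
  }
  if (length(unique(table$sample_id)) > 1L || length(unique(table$amplicon)) > 1L) {
    abort("`pattern_betas()` expects a single sample and amplicon; group and map over them.")
  }
  m <- pattern_to_matrix(table$pattern)
  w <- as.numeric(table$count)
  seen <- !is.na(m)
  n_calls <- as.integer(colSums(seen * w))
  meth <- colSums(ifelse(seen, m, 0L) * w)
  beta <- ifelse(n_calls > 0L, meth / n_calls, NA_real_)
  tibble::tibble(sample_id = table$sample_id[1L], amplicon = table$amplicon[1L],
                 cpg_index = seq_len(ncol(m)), beta = beta, n_calls = n_calls)
}

#' Pearson correlation of methylation between neighboring CpGs
#'
#' Computes, for every pair of CpGs in the amplicon, the Pearson
#' correlation of the binary methylation states across reads (expanded by
#' pattern count, using only reads non-missing at both CpGs). Coherently
#' modified strands give correlations near 1; stochastic, independent
#' modification gives correlations near 0. Pairs where either CpG has
#' zero variance are undefined (`NA`).
#'
#' @inheritParams pattern_betas
#' @return A symmetric `k x k` matrix of Pearson r with unit diagonal;
#'   dimnames are CpG indices.
#' @export
neighbor_correlation <- function(table) {
  table <- tibble::as_tibble(table)
  if (nrow(table) == 0L) abort("Empty pattern table.")
  m <- pattern_to_matrix(table$pattern)
  w <- as.numeric(table$count)
  k <- ncol(m)
  out <- matrix(NA_real_, k, k, dimnames = list(seq_len(k), seq_len(k)))
  diag(out) <- 1
  if (k < 2L) return(out)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      if (!any(ok)) next
      out[i, j] <- out[j, i] <- weighted_pearson(m[ok, i], m[ok, j], w[ok])
    }
  }
  out
}

# count-weighted Pearson correlation; NA when either margin is constant
weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  if (sw <= 0) return(NA_real_)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Call an amplicon's reads from a FASTQ file
#'
#' Reads a (optionally gzipped) FASTQ of per-sample amplicon reads,
#' calls them with [call_reads()] and returns both the per-read calls and
#' the aggregated [pattern_table()].
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @inheritParams call_reads
#' @inheritParams pattern_table
#' @return List with elements `calls` (per-read tibble), `table` (pattern
#'   table tibble) and `qc` (one-row tibble: reads in, reads passing,
#'   median conversion rate).
#' @export
call_fastq <- function(path, spec, sample_id, orient = c("auto", "forward")) {
  seqs <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  calls <- call_reads(seqs, spec, orient = orient)
  tab <- pattern_table(calls, sample_id, spec)
  qc <- tibble::tibble(
    sample_id = sample_id, amplicon = spec$name,
    n_reads = nrow(calls), n_passed = sum(calls$passed_qc),
    median_conversion = median(calls$conversion_rate, na.rm = TRUE)
  )
  list(calls = calls, table = tab, qc = qc)
}
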