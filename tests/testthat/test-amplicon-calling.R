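test_that("amplicon specs validate their CpG coordinates", {
  expect_s3_class(toy_amplicon(), "amplicon_spec")
  expect_error(amplicon("bad", "ACGTCGA", c(3)), "CG dinucleotide")
  expect_error(amplicon("bad", "ACGTCGA", c(5, 2)), "strictly increasing")
  expect_error(amplicon("bad", "ACGTCGA", c(2, 7)), "out of range")
})

test_that("default panel ships 4, 12 and 21 CpGs with valid coordinates", {
  panel <- default_panel()
  expect_named(panel, c("Prima1", "Hsf4", "Kcns1"))
  expect_equal(unname(vapply(panel, function(s) length(s$cpg_positions), 1L)),
               c(4L, 12L, 21L))
  for (spec in panel) {
    chars <- strsplit(spec$reference_seq, "")[[1]]
    expect_true(all(chars[spec$cpg_positions] == "C"))
    expect_true(all(chars[spec$cpg_positions + 1] == "G"))
    # no CpGs beyond the declared ones
    expect_equal(length(gregexpr("CG", spec$reference_seq, fixed = TRUE)[[1]]),
                 length(spec$cpg_positions))
    # non-CpG cytosines exist so conversion QC has a denominator
    expect_gt(sum(chars == "C") - length(spec$cpg_positions), 0)
  }
  # deterministic across calls
  expect_identical(default_panel(), panel)
})

test_that("call_reads applies the C/T rule at CpG sites", {
  amp <- toy_amplicon()
  calls <- call_reads(c("ATGTCGA", "ACGTCGA"), amp, orient = "forward")
  expect_equal(calls$pattern, c("01", "11"))

  # fully converted, fully unmethylated: every C (CpG or not) reads as T
  qc <- qc_amplicon()
  ref <- qc$reference_seq
  unmeth <- chartr("C", "T", ref)
  call_u <- call_reads(unmeth, qc, orient = "forward")
  expect_equal(call_u$pattern, "00")
  expect_equal(call_u$conversion_rate, 1)
  expect_true(call_u$passed_qc)

  # unconverted read identical to reference: all-methylated, conversion 0
  call_m <- call_reads(ref, qc, orient = "forward")
  expect_equal(call_m$pattern, "11")
  expect_equal(call_m$conversion_rate, 0)
  expect_false(call_m$passed_qc)  # fails the min_conversion QC
})

test_that("short reads get trailing missing calls; empty reads fail QC", {
  qc <- qc_amplicon()
  ref <- qc$reference_seq
  # read covering only the first CpG (positions 1..5)
  short <- chartr("C", "T", substr(ref, 1, 5))
  calls <- call_reads(short, qc, orient = "forward")
  expect_equal(calls$pattern, "0?")
  expect_true(calls$passed_qc)

  empty <- call_reads("", qc, orient = "forward")
  expect_false(empty$passed_qc)
  expect_equal(empty$pattern, "??")

  # garbage read: rejected by mismatch QC, not by crashing
  garbage <- call_reads(strrep("G", nchar(ref)), qc, orient = "forward")
  expect_false(garbage$passed_qc)
})

test_that("mismatch and conversion QC use the declared thresholds", {
  qc <- qc_amplicon(max_mismatch_frac = 0, min_conversion = 0.9)
  ref_conv <- chartr("C", "T", qc$reference_seq)
  # introduce one mismatch at a comparable (non-C) position
  bad <- ref_conv
  substr(bad, 2, 2) <- "G"  # reference A at position 2
  res <- call_reads(c(ref_conv, bad), qc, orient = "forward")
  expect_equal(res$passed_qc, c(TRUE, FALSE))
  expect_gt(res$mismatch_frac[2], 0)
})

test_that("reverse-complement (bottom strand) reads are recognized in auto mode", {
  qc <- qc_amplicon()
  ref <- qc$reference_seq
  top <- chartr("C", "T", ref)                     # unmethylated top-strand read
  chars <- strsplit(ref, "")[[1]]
  # unmethylated bottom-strand product: complement of ref with bottom Cs
  # (i.e. complement of every ref G) converted; then read 5'->3'
  comp <- chartr("ACGT", "TGCA", ref)
  bottom <- paste(rev(strsplit(chartr("C", "T", comp), "")[[1]]), collapse = "")
  res <- call_reads(c(top, bottom), qc)
  expect_equal(res$strand, c("+", "-"))
  expect_equal(res$pattern, c("00", "00"))
  expect_true(all(res$passed_qc))
})

test_that("pattern tables count only QC-passing reads and conserve totals", {
  amp <- toy_amplicon()
  calls <- tibble::tibble(
    pattern = c("10", "10", "00", "11", "1?", "1?"),
    passed_qc = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  tab <- pattern_table(calls, "s1", amp)
  expect_equal(sum(tab$count), 5L)
  expect_equal(tab$count[tab$pattern == "10"], 2L)
  expect_equal(tab$count[tab$pattern == "1?"], 1L)

  expect_warning(
    empty <- pattern_table(tibble::tibble(pattern = character(),
                                          passed_qc = logical()), "s1", amp),
    "No QC-passing reads")
  expect_equal(nrow(empty), 0L)
})

test_that("beta values equal the brute-force per-read indicator means", {
  tab <- tibble::tibble(sample_id = "s", amplicon = "a",
                        pattern = c("10", "01"), count = c(2L, 2L))
  expect_equal(pattern_betas(tab)$beta, c(0.5, 0.5))

  tab2 <- tibble::tibble(sample_id = "s", amplicon = "a",
                         pattern = c("11", "00"), count = c(3L, 1L))
  expect_equal(pattern_betas(tab2)$beta, c(0.75, 0.75))

  # missing calls drop out of the denominator
  tab3 <- tibble::tibble(sample_id = "s", amplicon = "a",
                         pattern = c("1?", "10"), count = c(4L, 4L))
  b3 <- pattern_betas(tab3)
  expect_equal(b3$beta, c(1, 0))
  expect_equal(b3$n_calls, c(8L, 4L))

  # brute-force equivalence on random tables (exact, integer counts)
  set.seed(11)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    pats <- unique(replicate(6, random_pattern(k)))
    pats <- pats[grepl("[01]", pats)]
    tab <- tibble::tibble(sample_id = "s", amplicon = "a", pattern = pats,
                          count = sample(1:50, length(pats), replace = TRUE))
    expect_equal(pattern_betas(tab)$beta, oracle_betas(tab))
  }
})

test_that("neighbor correlations recover coherent, anti-coherent and independent strands", {
  coherent <- tibble::tibble(sample_id = "s", amplicon = "a",
                             pattern = c("11", "00"), count = c(50L, 50L))
  expect_equal(neighbor_correlation(coherent)[1, 2], 1)

  anti <- tibble::tibble(sample_id = "s", amplicon = "a",
                         pattern = c("10", "01"), count = c(50L, 50L))
  expect_equal(neighbor_correlation(anti)[1, 2], -1)

  # i.i.d. Bernoulli(0.5) per CpG: correlations vanish at large n
  set.seed(3)
  k <- 3
  reads <- matrix(rbinom(10000 * k, 1, 0.5), ncol = k)
  pats <- apply(reads, 1, paste0, collapse = "")
  tab <- tibble::as_tibble(table(pats))
  tab <- tibble::tibble(sample_id = "s", amplicon = "a",
                        pattern = tab$pats, count = as.integer(tab$n))
  r <- neighbor_correlation(tab)
  expect_true(all(abs(r[upper.tri(r)]) < 0.05))
  expect_equal(diag(r), setNames(rep(1, k), 1:k))

  # zero variance at a CpG: undefined, flagged as NA, no crash
  const <- tibble::tibble(sample_id = "s", amplicon = "a",
                          pattern = c("10", "11"), count = c(5L, 5L))
  expect_true(is.na(neighbor_correlation(const)[1, 2]))
})

test_that("simulated pattern frequencies converge to the generating distribution", {
  # round trip: known pattern distribution -> reads -> call -> table
  probs <- c("11" = 0.4, "10" = 0.3, "01" = 0.2, "00" = 0.1)
  amp <- toy_amplicon()
  set.seed(5)
  n <- 50000
  drawn <- sample(names(probs), n, replace = TRUE, prob = probs)
  # render as converted sequences and call them back
  seq_for <- c("11" = "ACGTCGA", "10" = "ACGTTGA",
               "01" = "ATGTCGA", "00" = "ATGTTGA")
  calls <- call_reads(seq_for[drawn], amp, orient = "forward")
  tab <- pattern_table(calls, "s", amp)
  expect_equal(sum(tab$count), n)
  emp <- setNames(tab$count / n, tab$pattern)[names(probs)]
  tv <- sum(abs(emp - probs)) / 2
  expect_lt(tv, 0.02)
})
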