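# fixture builders shared across test files

toy_amplicon <- function() amplicon("toy", "ACGTCGA", c(2, 5))

# amplicon with non-CpG cytosines so conversion-rate QC is exercised:
# CpGs at 3 and 9; non-CpG Cs at 6 and 13
qc_amplicon <- function(...) {
  amplicon("qc", "TACGTCTACGTACTA", c(3, 9), ...)
}

# noise-free methylation matrix: Amp:1 is exactly affine in age
# (beta = 0.1 + 0.004 * age) so age lies in the design's column span and
# OLS clocks must interpolate exactly; Amp:2 and Amp:3 are fixed
# non-collinear columns
exact_matrix <- function(ages = c(10, 40, 70, 100, 130)) {
  stopifnot(length(ages) == 5L)
  tibble::tibble(
    sample_id = paste0("s", seq_along(ages)),
    age_weeks = ages,
    `Amp:1` = 0.1 + 0.004 * ages,
    `Amp:2` = c(0.35, 0.22, 0.41, 0.28, 0.33),
    `Amp:3` = c(0.15, 0.42, 0.27, 0.39, 0.21)
  )
}

# small random single-read model built directly from trajectories
random_srm <- function(k, epsilon = NULL) {
  epsilon <- epsilon %||% runif(1, 0.005, 0.1)
  traj <- tibble::tibble(
    cpg_id = paste0("R:", seq_len(k)),
    amplicon = "R",
    cpg_index = seq_len(k),
    slope = runif(k, -0.004, 0.006),
    intercept = runif(k, -0.1, 0.9),
    pearson_r = NA_real_, r_squared = NA_real_, n_samples = 10L
  )
  readclock:::new_single_read_model("R", traj, epsilon)
}

random_pattern <- function(k, p_missing = 0.15) {
  chars <- sample(c("0", "1", "?"), k, replace = TRUE,
                  prob = c((1 - p_missing) / 2, (1 - p_missing) / 2, p_missing))
  paste0(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
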