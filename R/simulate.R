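#' Simulation panel: per-CpG aging trajectories for synthetic cohorts
#'
#' Builds the generating model for synthetic stochastic-aging cohorts.
#' Each amplicon gets a bell-shaped profile of age-association across its
#' CpGs: the slope of CpG i is
#' `peak_slope * exp(-(i - center)^2 / (2 * width^2))`, so the central
#' CpG ages fastest and the association decays towards the amplicon
#' edges, as observed at age-associated regions. Baselines are the
#' methylation fraction at age 0.
#'
#' @param params Tibble of per-amplicon generator settings with columns
#'   `amplicon`, `center_index`, `profile_width`, `peak_slope`
#'   (beta-fraction per week), `baseline` (beta fraction at age 0),
#'   `noise_sd` (per-sample, per-CpG Gaussian noise on the methylation
#'   probability). Default [default_sim_params()].
#' @param inter_cpg_rho Latent correlation in \[0, 1) between CpGs of a
#'   read (shared-latent Gaussian-threshold scheme); 0 (default) gives
#'   fully independent per-CpG Bernoulli methylation within reads.
#' @param specs Named list of [amplicon()] specs providing sequences and
#'   CpG coordinates; default [default_panel()]. Must cover every
#'   amplicon in `params`.
#' @return A `sim_panel` object.
#' @export
sim_panel <- function(params = default_sim_params(), inter_cpg_rho = 0,
                      specs = default_panel()) {
  params <- tibble::as_tibble(params)
  req <- c("amplicon", "center_index", "profile_width", "peak_slope",
           "baseline", "noise_sd")
  miss <- setdiff(req, names(params))
  if (length(miss)) abort(paste0("`params` missing columns: ",
                                 paste(miss, collapse = ", ")))
  if (!is.numeric(inter_cpg_rho) || inter_cpg_rho < 0 || inter_cpg_rho >= 1) {
    abort("`inter_cpg_rho` must lie in [0, 1).")
  }
  missing_specs <- setdiff(params$amplicon, names(specs))
  if (length(missing_specs)) {
    abort(paste0("No amplicon spec for: ", paste(missing_specs, collapse = ", ")))
  }
  amplicons <- purrr::pmap(params, function(amplicon, center_index,
                                            profile_width, peak_slope,
                                            baseline, noise_sd) {
    spec <- specs[[amplicon]]
    i <- seq_along(spec$cpg_positions)
    slopes <- if (profile_width == 0) {
      ifelse(i == center_index, peak_slope, 0)
    } else {
      peak_slope * exp(-(i - center_index)^2 / (2 * profile_width^2))
    }
    top <- baseline + slopes * 200
    if (any(top > 1.05) || baseline < -0.05) {
      warn(sprintf("Amplicon '%s': trajectories escape [0, 1] by more than 0.05 over the age grid; values will be clipped.",
                   amplicon))
    }
    list(spec = spec, slopes = slopes,
         baselines = rep(baseline, length(i)), noise_sd = noise_sd)
  })
  names(amplicons) <- params$amplicon
  structure(list(params = params, amplicons = amplicons,
                 inter_cpg_rho = inter_cpg_rho),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("<sim_panel> %d amplicon(s), inter-CpG rho = %.2f\n",
              length(x$amplicons), x$inter_cpg_rho))
  print(x$params)
  invisible(x)
}

#' @describeIn sim_panel Realized per-CpG generating trajectories
#'   (`cpg_id`, `amplicon`, `cpg_index`, `slope`, `intercept`,
#'   `noise_sd`).
#' @param x A `sim_panel`.
#' @param ... Unused.
#' @method tidy sim_panel
#' @export
tidy.sim_panel <- function(x, ...) {
  purrr::imap(x$amplicons, function(a, nm) {
    tibble::tibble(cpg_id = cpg_ids(a$spec), amplicon = nm,
                   cpg_index = seq_along(a$slopes),
                   slope = a$slopes, intercept = a$baselines,
                   noise_sd = a$noise_sd)
  }) |>
    dplyr::bind_rows()
}

#' Default generator settings for the three-amplicon panel
#'
#' One row per amplicon of [default_panel()]. Centers sit mid-amplicon
#' (symmetric bell), widths scale with CpG count, the peak slope of
#' 0.0045 beta-fraction per week spans roughly half the beta range over
#' a 0--130-week mouse lifespan from a baseline of 0.10, and the
#' per-sample trajectory noise of 0.03 beta-fraction matches the
#' between-mouse scatter the clocks have to tolerate.
#'
#' @return Tibble of generator settings (see [sim_panel()]).
#' @export
default_sim_params <- function() {
  tibble::tribble(
    ~amplicon, ~center_index, ~profile_width, ~peak_slope, ~baseline, ~noise_sd,
    "Prima1",  2.5,           1.5,            0.0045,      0.10,      0.03,
    "Hsf4",    6.5,           3,              0.0045,      0.10,      0.03,
    "Kcns1",   11,            4,              0.0045,      0.10,      0.03
  )
}

#' Strain age transforms
#'
#' Maps chronological age to the effective epigenetic age of a strain:
#' identity for the reference strain (C57BL/6-like), `s * a` for a
#' linearly accelerated strain, or `A * log(1 + a / tau)` for a
#' logarithmically accelerated strain (DBA/2-like; smooth at age 0). The
#' logarithmic defaults `A = 55`, `tau = 15` keep the effective age
#' above chronological age across a 5--120-week range while flattening
#' towards old age.
#'
#' @param form `"identity"`, `"linear"` or `"logarithmic"`.
#' @param s Linear acceleration factor (default 1.5).
#' @param A,tau Logarithmic transform parameters (weeks).
#' @return A function mapping age in weeks to effective age in weeks,
#'   with a `"label"` attribute.
#' @export
strain_transform <- function(form = c("identity", "linear", "logarithmic"),
                             s = 1.5, A = 55, tau = 15) {
  form <- match.arg(form)
  f <- switch(form,
    identity = function(a) a,
    linear = {
      if (!is.finite(s) || s <= 0) abort("`s` must be positive and finite.")
      function(a) s * a
    },
    logarithmic = {
      if (!is.finite(A) || A <= 0 || !is.finite(tau) || tau <= 0) {
        abort("`A` and `tau` must be positive and finite.")
      }
      function(a) A * log(1 + a / tau)
    }
  )
  attr(f, "label") <- form
  f
}

#' Simulate a stochastic-aging mouse cohort
#'
#' Draws `n_mice` chronological ages uniformly over `age_range`, maps
#' them through the strain transform to effective ages, realizes each
#' sample's per-CpG methylation probability
#' `q_i = clip(baseline_i + slope_i * a_eff + N(0, noise_sd), 0, 1)`,
#' and draws `reads_per_amplicon` binary reads per amplicon: independent
#' Bernoulli(q_i) per CpG when `inter_cpg_rho = 0`, or coupled through a
#' per-read shared latent Gaussian when the panel's rho is positive.
#' Identical `(panel, arguments, seed)` give bit-identical cohorts.
#'
#' @param panel A [sim_panel()].
#' @param n_mice Number of animals.
#' @param age_range Chronological age range in weeks, default `c(5, 120)`.
#' @param reads_per_amplicon Reads simulated per amplicon per sample
#'   (default 2000, typical deep-amplicon coverage).
#' @param transform A [strain_transform()] (default identity).
#' @param strain Strain label recorded in the metadata.
#' @param id_prefix Prefix for sample ids.
#' @param seed Integer seed (required).
#' @return A `sim_cohort`: list with `samples` (metadata tibble including
#'   effective ages), `truth` (methylation matrix tibble of the true
#'   per-sample probabilities `q`), `patterns` (combined pattern-table
#'   tibble over all samples and amplicons) and the generating `panel`,
#'   `seed` and call parameters.
#' @export
simulate_cohort <- function(panel, n_mice, age_range = c(5, 120),
                            reads_per_amplicon = 2000L,
                            transform = strain_transform("identity"),
                            strain = "C57BL/6", id_prefix = strain,
                            seed) {
  stopifnot(inherits(panel, "sim_panel"))
  if (missing(seed)) abort("`seed` is required for a reproducible cohort.")
  if (n_mice < 1L) abort("`n_mice` must be at least 1.")
  if (length(age_range) != 2L || age_range[1L] > age_range[2L] ||
      age_range[1L] < 0) {
    abort("`age_range` must be c(min, max) with 0 <= min <= max.")
  }
  rho <- panel$inter_cpg_rho
  with_seed(seed, {
    ages <- runif(n_mice, age_range[1L], age_range[2L])
    eff <- transform(ages)
    if (any(!is.finite(eff))) abort("Strain transform produced non-finite ages.")
    ids <- sprintf("%s_%03d", gsub("[^A-Za-z0-9]+", "", id_prefix),
                   seq_len(n_mice))
    samples <- tibble::tibble(sample_id = ids, age_weeks = ages,
                              effective_age_weeks = eff, strain = strain)

    truth_rows <- vector("list", n_mice)
    pattern_rows <- list()
    for (s in seq_len(n_mice)) {
      qs <- list()
      for (nm in names(panel$amplicons)) {
        amp <- panel$amplicons[[nm]]
        k <- length(amp$slopes)
        q <- clip(amp$baselines + amp$slopes * eff[s] +
                    rnorm(k, 0, amp$noise_sd), 0, 1)
        qs[[nm]] <- setNames(q, cpg_ids(amp$spec))
        reads <- draw_reads(q, reads_per_amplicon, rho)
        pat <- matrix_to_pattern(reads)
        tab <- tibble::as_tibble(table(pat))
        pattern_rows[[length(pattern_rows) + 1L]] <-
          tibble::tibble(sample_id = ids[s], amplicon = nm,
                         pattern = tab$pat, count = as.integer(tab$n))
      }
      truth_rows[[s]] <- tibble::as_tibble(as.list(unlist(unname(qs))))
    }
    truth <- dplyr::bind_cols(
      samples[, c("sample_id", "age_weeks", "strain")],
      dplyr::bind_rows(truth_rows)
    )
    patterns <- dplyr::bind_rows(pattern_rows) |>
      dplyr::arrange(.data$sample_id, .data$amplicon,
                     dplyr::desc(.data$count), .data$pattern)
    structure(
      list(samples = samples, truth = truth, patterns = patterns,
           panel = panel, seed = as.integer(seed),
           config = list(n_mice = n_mice, age_range = age_range,
                         reads_per_amplicon = as.integer(reads_per_amplicon),
                         transform = attr(transform, "label") %||% "custom",
                         strain = strain)),
      class = "sim_cohort"
    )
  })
}

# binary read matrix: reads x CpGs. rho couples CpGs of a read through a
# shared standard-normal latent; marginals stay Bernoulli(q_i)
draw_reads <- function(q, n_reads, rho) {
  k <- length(q)
  if (rho == 0) {
    m <- matrix(rbinom(n_reads * k, 1L, rep(q, each = n_reads)),
                nrow = n_reads, ncol = k)
  } else {
    shared <- rnorm(n_reads)
    z <- sqrt(rho) * shared +
      sqrt(1 - rho) * matrix(rnorm(n_reads * k), n_reads, k)
    thresh <- matrix(qnorm(q), n_reads, k, byrow = TRUE)
    m <- (z < thresh) * 1L
  }
  m
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d mice (%s, %s transform), ages %.0f-%.0f weeks, %d reads/amplicon, seed %d\n",
              x$config$n_mice, x$config$strain, x$config$transform,
              min(x$samples$age_weeks), max(x$samples$age_weeks),
              x$config$reads_per_amplicon, x$seed))
  invisible(x)
}

#' Write a simulated cohort as bisulfite-converted FASTQ
#'
#' Renders every simulated read as a bisulfite-converted sequence on the
#' amplicon reference: non-CpG cytosines read as T (less an optional
#' conversion-failure fraction that stays C), CpG cytosines read as C
#' when methylated and T when unmethylated. One FASTQ file is written
#' per sample and amplicon, with constant base quality. With
#' `conversion_failure = 0` a round trip through [call_reads()] and
#' [pattern_table()] recovers the generating pattern tables exactly.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @param conversion_failure Probability that a non-CpG C escapes
#'   conversion and still reads as C (default 0).
#' @param gzip Compress output files (default `FALSE`).
#' @return Manifest tibble: `sample_id`, `amplicon`, `age_weeks`,
#'   `strain`, `n_reads`, `path`.
#' @export
cohort_fastq <- function(cohort, out_dir, conversion_failure = 0,
                         gzip = FALSE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  stopifnot_scalar_fraction(conversion_failure, "conversion_failure")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(cohort$seed + 1L, {
    rows <- cohort$patterns |>
      dplyr::group_by(.data$sample_id, .data$amplicon) |>
      dplyr::group_map(function(tab, key) {
        spec <- cohort$panel$amplicons[[key$amplicon]]$spec
        seqs <- render_reads(tab$pattern, tab$count, spec, conversion_failure)
        path <- file.path(out_dir, sprintf("%s_%s.fastq%s", key$sample_id,
                                           key$amplicon,
                                           if (gzip) ".gz" else ""))
        write_fastq_file(seqs, path,
                         prefix = paste0(key$sample_id, "_", key$amplicon))
        tibble::tibble(sample_id = key$sample_id, amplicon = key$amplicon,
                       n_reads = length(seqs), path = path)
      }) |>
      dplyr::bind_rows()
  })
  dplyr::left_join(rows,
                   cohort$samples[, c("sample_id", "age_weeks", "strain")],
                   by = "sample_id") |>
    dplyr::relocate("sample_id", "amplicon", "age_weeks", "strain")
}

# expand patterns by count and render each as a converted read sequence
render_reads <- function(patterns, counts, spec, conversion_failure) {
  ref <- strsplit(spec$reference_seq, "", fixed = TRUE)[[1L]]
  L <- length(ref)
  is_cpg_c <- rep(FALSE, L); is_cpg_c[spec$cpg_positions] <- TRUE
  non_cpg_c <- which(ref == "C" & !is_cpg_c)
  base <- ref
  base[non_cpg_c] <- "T"

  pat <- pattern_to_matrix(rep(patterns, counts))
  n <- nrow(pat)
  M <- matrix(base, nrow = n, ncol = L, byrow = TRUE)
  for (j in seq_along(spec$cpg_positions)) {
    col <- spec$cpg_positions[j]
    M[, col] <- ifelse(is.na(pat[, j]), "N",
                       ifelse(pat[, j] == 1L, "C", "T"))
  }
  if (conversion_failure > 0 && length(non_cpg_c)) {
    fail <- matrix(runif(n * length(non_cpg_c)) < conversion_failure,
                   nrow = n)
    sub <- M[, non_cpg_c, drop = FALSE]
    sub[fail] <- "C"
    M[, non_cpg_c] <- sub
  }
  apply(M, 1L, paste0, collapse = "")
}

write_fastq_file <- function(seqs, path, prefix) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("%s_read%05d", prefix, seq_along(seqs))
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Assemble a methylation matrix from pattern tables
#'
#' Aggregates per-read pattern tables to per-CpG beta values
#' ([pattern_betas()]) for every sample and amplicon, pivots them into
#' the samples-by-CpG matrix layout used by the clock trainers, and joins
#' sample metadata.
#'
#' @param patterns Pattern-table tibble covering one or more samples and
#'   amplicons (`sample_id`, `amplicon`, `pattern`, `count`).
#' @param samples Metadata tibble with `sample_id`, `age_weeks` and
#'   optionally `strain`.
#' @return Methylation matrix tibble: `sample_id`, `age_weeks`,
#'   (`strain`,) then one `"amplicon:index"` beta column per CpG.
#' @export
methylation_matrix <- function(patterns, samples) {
  patterns <- tibble::as_tibble(patterns)
  samples <- tibble::as_tibble(samples)
  if (!all(c("sample_id", "age_weeks") %in% names(samples))) {
    abort("`samples` must have `sample_id` and `age_weeks` columns.")
  }
  betas <- patterns |>
    dplyr::group_by(.data$sample_id, .data$amplicon) |>
    dplyr::group_map(function(tab, key) {
      pattern_betas(dplyr::mutate(tab, sample_id = key$sample_id,
                                  amplicon = key$amplicon))
    }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(cpg_id = paste0(.data$amplicon, ":", .data$cpg_index)) |>
    dplyr::select("sample_id", "cpg_id", "beta") |>
    tidyr::pivot_wider(names_from = "cpg_id", values_from = "beta")
  keep <- intersect(c("sample_id", "age_weeks", "strain"), names(samples))
  dplyr::inner_join(samples[, keep], betas, by = "sample_id")
}

#' Age estimates from the generating inverse model
#'
#' For simulated cohorts the generator's own trajectories define the
#' best-case ("noise floor") age estimate: with known slopes `s_i` and
#' baselines `b_i`, least squares in the age direction gives
#' `a_hat = sum(s_i * (beta_i - b_i)) / sum(s_i^2)` over the chosen
#' CpGs. Trained clocks are benchmarked against this oracle in the
#' recovery tests.
#'
#' @param panel The generating [sim_panel()].
#' @param mat Methylation matrix tibble of observed betas.
#' @param cpg_ids CpG columns to use (character vector or tibble with a
#'   `cpg_id` column).
#' @return Tibble `sample_id`, `age_weeks` (if present), `oracle_age_weeks`.
#' @export
generating_inverse_ages <- function(panel, mat, cpg_ids) {
  stopifnot(inherits(panel, "sim_panel"))
  if (is.data.frame(cpg_ids)) cpg_ids <- cpg_ids$cpg_id
  traj <- tidy(panel)
  traj <- traj[match(cpg_ids, traj$cpg_id), ]
  if (anyNA(traj$slope)) {
    abort("Some `cpg_ids` are not part of the generating panel.")
  }
  mat <- tibble::as_tibble(mat)
  X <- as.matrix(mat[, cpg_ids, drop = FALSE])
  a_hat <- as.numeric((X - matrix(traj$intercept, nrow(X), ncol(X),
                                  byrow = TRUE)) %*% traj$slope /
                        sum(traj$slope^2))
  out <- tibble::tibble(oracle_age_weeks = a_hat)
  for (col in c("age_weeks", "sample_id")) {
    if (col %in% names(mat)) out <- dplyr::bind_cols(mat[col], out)
  }
  out
}
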