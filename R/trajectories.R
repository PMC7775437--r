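#  per-CpG DNAm-vs-age trajectories and CpG selection
#
#  The "methylation matrix" used throughout is a tibble with one row per
#  sample: `sample_id`, `age_weeks`, optionally `strain`, and one column
#  per CpG named "<amplicon>:<index>" holding beta fractions in [0, 1].

meta_cols <- c("sample_id", "age_weeks", "strain")

cpg_cols <- function(mat) setdiff(names(mat), meta_cols)

split_cpg_id <- function(cpg_id) {
  m <- regmatches(cpg_id, regexec("^(.*):([0-9]+)$", cpg_id))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort(paste0("Malformed CpG id(s): ", paste(cpg_id[bad], collapse = ", "),
                 " (expected \"amplicon:index\")."))
  }
  tibble::tibble(cpg_id = cpg_id,
                 amplicon = vapply(m, `[`, "", 2L),
                 cpg_index = as.integer(vapply(m, `[`, "", 3L)))
}

#' Fit the linear DNAm-versus-age trajectory of one CpG
#'
#' Ordinary least squares of beta (methylation fraction) on chronological
#' age in weeks. The slope is in beta-fraction per week; the Pearson
#' correlation with age is the statistic used for CpG selection and for
#' the positional correlation profiles along an amplicon.
#'
#' @param betas Numeric vector of beta fractions (may contain `NA`).
#' @param ages Chronological ages in weeks, same length.
#' @param cpg_id Optional identifier recorded in the result.
#' @return One-row tibble: `cpg_id`, `slope`, `intercept`, `pearson_r`,
#'   `r_squared`, `n_samples`. With zero variance in beta the slope is 0
#'   and the correlation is undefined (`NA`).
#' @examples
#' fit_cpg_trajectory(c(0.10, 0.20, 0.30), c(0, 100, 200))
#' @export
fit_cpg_trajectory <- function(betas, ages, cpg_id = NA_character_) {
  if (length(betas) != length(ages)) abort("`betas` and `ages` must have equal length.")
  ok <- is.finite(betas) & is.finite(ages)
  b <- betas[ok]; a <- ages[ok]
  if (length(b) < 3L) abort("At least 3 samples with non-missing beta are required.")
  if (sd(a) == 0) abort("Ages must not all be equal.")
  sxx <- sum((a - mean(a))^2)
  sxy <- sum((a - mean(a)) * (b - mean(b)))
  slope <- sxy / sxx
  intercept <- mean(b) - slope * mean(a)
  r <- if (sd(b) == 0) NA_real_ else sxy / sqrt(sxx * sum((b - mean(b))^2))
  tibble::tibble(cpg_id = cpg_id, slope = slope, intercept = intercept,
                 pearson_r = r, r_squared = r^2, n_samples = length(b))
}

#' Fit age trajectories for every CpG of a methylation matrix
#'
#' @param mat Methylation matrix tibble: `sample_id`, `age_weeks`,
#'   optional `strain`, plus one `"amplicon:index"` beta column per CpG.
#' @return Tibble with one row per CpG: `cpg_id`, `amplicon`,
#'   `cpg_index`, `slope`, `intercept`, `pearson_r`, `r_squared`,
#'   `n_samples`, ordered by amplicon and position.
#' @export
fit_cpg_trajectories <- function(mat) {
  mat <- tibble::as_tibble(mat)
  ids <- cpg_cols(mat)
  if (length(ids) == 0L) abort("`mat` has no CpG columns.")
  if (!"age_weeks" %in% names(mat)) abort("`mat` must have an `age_weeks` column.")
  fits <- purrr::map(ids, function(id) {
    fit_cpg_trajectory(mat[[id]], mat$age_weeks, cpg_id = id)
  })
  dplyr::bind_rows(fits) |>
    dplyr::select(-"cpg_id") |>
    dplyr::bind_cols(split_cpg_id(ids)) |>
    dplyr::relocate("cpg_id", "amplicon", "cpg_index") |>
    dplyr::arrange(.data$amplicon, .data$cpg_index)
}

#' Select the most age-associated CpGs per amplicon
#'
#' For each amplicon, ranks CpGs by the absolute Pearson correlation of
#' their DNAm level with chronological age and keeps the top
#' `per_amplicon`. Ties are broken deterministically by the lower CpG
#' index. With the default `per_amplicon = 1` and the three-amplicon
#' panel this reproduces the classic 3-CpG clock design (one best CpG in
#' each of Prima1, Hsf4 and Kcns1).
#'
#' @inheritParams fit_cpg_trajectories
#' @param per_amplicon Number of CpGs to keep per amplicon (default 1).
#' @return Tibble of the selected CpGs (columns as in
#'   [fit_cpg_trajectories()]), ordered by amplicon and position.
#'   Amplicons where every correlation is undefined are excluded with a
#'   warning.
#' @export
select_top_cpgs <- function(mat, per_amplicon = 1L) {
  traj <- fit_cpg_trajectories(mat)
  dropped <- traj |>
    dplyr::group_by(.data$amplicon) |>
    dplyr::filter(all(is.na(.data$pearson_r))) |>
    dplyr::ungroup()
  if (nrow(dropped) > 0L) {
    warn(paste0("Amplicon(s) with no defined age correlation excluded: ",
                paste(unique(dropped$amplicon), collapse = ", ")))
  }
  traj |>
    dplyr::filter(!is.na(.data$pearson_r)) |>
    dplyr::group_by(.data$amplicon) |>
    dplyr::arrange(dplyr::desc(abs(.data$pearson_r)), .data$cpg_index,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = per_amplicon) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$amplicon, .data$cpg_index)
}

#' Positional profile of CpG-age correlation along an amplicon
#'
#' The Pearson correlation of DNAm with chronological age, per CpG, in
#' amplicon order: plotted against CpG position this typically follows a
#' bell shape around the most age-associated site of a region.
#'
#' @inheritParams fit_cpg_trajectories
#' @param amplicon Optional amplicon name to restrict to.
#' @return Tibble `amplicon`, `cpg_index`, `cpg_id`, `pearson_r`,
#'   `r_squared`, ordered by position.
#' @export
cpg_age_profile <- function(mat, amplicon = NULL) {
  traj <- fit_cpg_trajectories(mat)
  if (!is.null(amplicon)) {
    traj <- dplyr::filter(traj, .data$amplicon %in% !!amplicon)
    if (nrow(traj) == 0L) abort(sprintf("No CpGs found for amplicon '%s'.", amplicon))
  }
  dplyr::select(traj, "amplicon", "cpg_index", "cpg_id", "pearson_r",
                "r_squared")
}
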