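#  readers/writers for the on-disk formats
#
#  Convention: DNAm levels are percent (0-100) on disk, matching how the
#  assays report them, and beta fractions [0, 1] in memory; conversion
#  happens here and only here.

CLOCK_JSON_SCHEMA <- "readclock/clock-model/1"
SRM_JSON_SCHEMA <- "readclock/single-read-model/1"

#' Read and write methylation-level CSV
#'
#' The beta CSV carries one row per sample: `sample_id`, `age_weeks`,
#' optionally `strain`, then one column per CpG (`"amplicon:index"`)
#' holding DNAm levels in percent. On reading, percent values are
#' converted to beta fractions; malformed cells (non-numeric, outside
#' \[0, 100\]) become missing with a warning.
#'
#' @param path File path.
#' @return `read_beta_csv()`: a methylation matrix tibble (fractions).
#' @export
read_beta_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  req <- c("sample_id", "age_weeks")
  miss <- setdiff(req, names(df))
  if (length(miss)) abort(paste0("Beta CSV is missing required column(s): ",
                                 paste(miss, collapse = ", ")))
  df$age_weeks <- as.numeric(df$age_weeks)
  if (any(!is.finite(df$age_weeks)) || any(df$age_weeks < 0)) {
    abort("`age_weeks` must be finite and non-negative.")
  }
  for (col in cpg_cols(df)) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- (!is.na(df[[col]]) & is.na(vals)) |
      (!is.na(vals) & (vals < 0 | vals > 100))
    if (any(bad)) {
      warn(sprintf("Column '%s': %d malformed or out-of-range cell(s) set to missing.",
                   col, sum(bad)))
      vals[bad] <- NA_real_
    }
    df[[col]] <- vals / 100
  }
  tibble::as_tibble(df)
}

#' @rdname read_beta_csv
#' @param mat Methylation matrix tibble (beta fractions in memory).
#' @return `write_beta_csv()`: the path, invisibly.
#' @export
write_beta_csv <- function(mat, path) {
  mat <- tibble::as_tibble(mat)
  out <- mat
  for (col in cpg_cols(out)) out[[col]] <- out[[col]] * 100
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write pattern-table TSV
#'
#' Tab-separated with columns `sample_id`, `amplicon`, `pattern` (string
#' over `0`/`1`/`?`) and `count`.
#'
#' @param path File path.
#' @return `read_pattern_tsv()`: pattern-table tibble.
#' @export
read_pattern_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          amplicon = readr::col_character(),
                          pattern = readr::col_character(),
                          count = readr::col_integer()))
  req <- c("sample_id", "amplicon", "pattern", "count")
  miss <- setdiff(req, names(df))
  if (length(miss)) abort(paste0("Pattern TSV is missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (any(df$count <= 0)) abort("Pattern counts must be positive.")
  if (any(grepl("[^01?]", df$pattern))) {
    abort("Patterns may only contain '0', '1' and '?'.")
  }
  df
}

#' @rdname read_pattern_tsv
#' @param patterns Pattern-table tibble.
#' @return `write_pattern_tsv()`: the path, invisibly.
#' @export
write_pattern_tsv <- function(patterns, path) {
  readr::write_tsv(tibble::as_tibble(patterns), path)
  invisible(path)
}

#' Read and write clock models as JSON
#'
#' Serializes a [clock_model] with stable field order and full numeric
#' precision; reading a file with a different schema version is an
#' explicit error. The round trip reproduces the model exactly.
#'
#' @param path File path.
#' @return `read_clock_json()`: a [clock_model].
#' @export
read_clock_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, CLOCK_JSON_SCHEMA)) {
    abort(sprintf("Unsupported clock JSON schema '%s' (expected '%s').",
                  x$schema %||% "<none>", CLOCK_JSON_SCHEMA))
  }
  terms <- tibble::as_tibble(x$terms)
  if (nrow(terms) == 0L) {
    terms <- tibble::tibble(cpg_id = character(), coefficient = double())
  }
  meta <- x$meta
  meta$lambda <- meta$lambda %||% NULL
  new_clock_model(kind = x$kind, terms = terms, intercept = x$intercept,
                  meta = meta)
}

#' @rdname read_clock_json
#' @param model A [clock_model].
#' @return `write_clock_json()`: the path, invisibly.
#' @export
write_clock_json <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  payload <- list(
    schema = CLOCK_JSON_SCHEMA,
    kind = model$kind,
    terms = model$terms,
    intercept = model$intercept,
    meta = model$meta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read and write single-read models as JSON
#'
#' Stores the amplicon name, epsilon and the per-CpG trajectory table of
#' a [single_read_model()]; the age grid and likelihood tables are
#' rebuilt on reading, so the round trip reproduces predictions exactly.
#'
#' @param path File path.
#' @return `read_single_read_json()`: a `single_read_model`.
#' @export
read_single_read_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, SRM_JSON_SCHEMA)) {
    abort(sprintf("Unsupported single-read model schema '%s' (expected '%s').",
                  x$schema %||% "<none>", SRM_JSON_SCHEMA))
  }
  new_single_read_model(x$amplicon, tibble::as_tibble(x$trajectories),
                        x$epsilon)
}

#' @rdname read_single_read_json
#' @param model A `single_read_model`.
#' @return `write_single_read_json()`: the path, invisibly.
#' @export
write_single_read_json <- function(model, path) {
  stopifnot(inherits(model, "single_read_model"))
  payload <- list(schema = SRM_JSON_SCHEMA, amplicon = model$amplicon,
                  epsilon = model$epsilon,
                  trajectories = model$trajectories)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read and write read-age distribution CSV
#'
#' Wide layout for heatmap rendering: one row per sample and amplicon,
#' columns `age_0` ... `age_200` holding relative read frequencies
#' (linear scale; each row sums to 1).
#'
#' @param path File path.
#' @return `read_distribution_csv()`: long tibble (`sample_id`,
#'   `amplicon`, `age`, `frequency`).
#' @export
read_distribution_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  age_cols <- grep("^age_[0-9]+$", names(df), value = TRUE)
  if (!length(age_cols)) abort("No `age_<n>` columns found in distribution CSV.")
  tidyr::pivot_longer(df, dplyr::all_of(age_cols), names_to = "age",
                      values_to = "frequency") |>
    dplyr::mutate(age = as.integer(sub("^age_", "", .data$age))) |>
    dplyr::arrange(.data$sample_id, .data$amplicon, .data$age)
}

#' @rdname read_distribution_csv
#' @param dist Long distribution tibble (`sample_id`, `amplicon`, `age`,
#'   `frequency`), e.g. bound rows of [predict_sample_age()]
#'   distributions.
#' @return `write_distribution_csv()`: the path, invisibly.
#' @export
write_distribution_csv <- function(dist, path) {
  wide <- tibble::as_tibble(dist) |>
    dplyr::mutate(age = sprintf("age_%d", .data$age)) |>
    tidyr::pivot_wider(names_from = "age", values_from = "frequency")
  readr::write_csv(wide, path)
  invisible(path)
}

#' Read and write amplicon panels as YAML
#'
#' A panel file is a list of amplicons, each with `name`, `sequence` and
#' 1-based `cpg_positions`, plus optional QC thresholds.
#'
#' @param path File path.
#' @return `read_panel_yaml()`: named list of [amplicon()] specs.
#' @export
read_panel_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  specs <- purrr::map(x$amplicons, function(a) {
    amplicon(a$name, a$sequence, unlist(a$cpg_positions),
             max_mismatch_frac = a$max_mismatch_frac %||% 0.1,
             min_conversion = a$min_conversion %||% 0.9)
  })
  names(specs) <- purrr::map_chr(specs, "name")
  specs
}

#' @rdname read_panel_yaml
#' @param specs Named list of [amplicon()] specs.
#' @return `write_panel_yaml()`: the path, invisibly.
#' @export
write_panel_yaml <- function(specs, path) {
  payload <- list(amplicons = purrr::map(unname(specs), function(s) {
    list(name = s$name, sequence = s$reference_seq,
         cpg_positions = as.integer(s$cpg_positions),
         max_mismatch_frac = s$max_mismatch_frac,
         min_conversion = s$min_conversion)
  }))
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' Read ddPCR well counts from CSV
#'
#' Columns: `sample_id`, `target`, `n_droplets`, `pos_meth`,
#' `pos_unmeth`.
#'
#' @param path File path.
#' @return Tibble of wells, ready for [ddpcr_estimate()].
#' @export
read_ddpcr_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("n_droplets", "pos_meth", "pos_unmeth")
  miss <- setdiff(req, names(df))
  if (length(miss)) abort(paste0("ddPCR CSV is missing column(s): ",
                                 paste(miss, collapse = ", ")))
  tibble::as_tibble(df)
}
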