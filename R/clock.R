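#' Epigenetic clock models
#'
#' A clock model is a linear predictor of chronological age (weeks) from
#' beta fractions at named CpGs: `age = intercept + sum(coef_j * beta_j)`.
#' Two trainers are provided: [train_multivariable()] (ordinary least
#' squares on a handful of pre-selected CpGs, the classic 3-CpG design)
#' and [train_lasso()] (L1-penalized regression over all CpGs with the
#' penalty chosen by cross-validation, the machine-learning design).
#'
#' @name clock_model
NULL

new_clock_model <- function(kind, terms, intercept, meta) {
  structure(list(kind = kind, terms = terms, intercept = intercept,
                 meta = meta),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %s: %d CpG term(s), intercept %.3f weeks (n = %d)\n",
              x$kind, nrow(x$terms), x$intercept, x$meta$n))
  print(x$terms, n = 10)
  invisible(x)
}

#' @describeIn clock_model One row per model term (broom convention:
#'   `term`, `estimate`), the intercept first.
#' @param x A `clock_model`.
#' @param ... Unused.
#' @method tidy clock_model
#' @export
tidy.clock_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$terms$cpg_id),
                 estimate = c(x$intercept, x$terms$coefficient))
}

#' @describeIn clock_model One-row model summary (`kind`, `n_terms`,
#'   training `n`, `lambda`, `cv_folds`, `seed`).
#' @method glance clock_model
#' @export
glance.clock_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_terms = nrow(x$terms), n = x$meta$n,
                 lambda = x$meta$lambda %||% NA_real_,
                 cv_folds = x$meta$folds %||% NA_integer_,
                 seed = x$meta$seed %||% NA_integer_)
}

# extract and validate the design matrix for the given CpG ids; rows with
# any missing selected beta are dropped (not imputed) with a message
clock_design <- function(mat, cpg_ids) {
  mat <- tibble::as_tibble(mat)
  if (is.data.frame(cpg_ids)) cpg_ids <- cpg_ids$cpg_id
  cpg_ids <- as.character(cpg_ids)
  missing_cols <- setdiff(cpg_ids, names(mat))
  if (length(missing_cols)) {
    abort(paste0("CpG column(s) absent from the matrix: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"age_weeks" %in% names(mat)) abort("`mat` must have an `age_weeks` column.")
  X <- as.matrix(mat[, cpg_ids, drop = FALSE])
  keep <- stats::complete.cases(X) & is.finite(mat$age_weeks)
  if (any(!keep)) {
    message(sprintf("Dropping %d row(s) with missing beta in selected CpGs.",
                    sum(!keep)))
  }
  list(X = X[keep, , drop = FALSE], age = mat$age_weeks[keep],
       n_dropped = sum(!keep))
}

#' Train a multivariable linear clock
#'
#' Ordinary least squares of chronological age on the beta fractions of
#' the selected CpGs (typically the single most age-associated CpG of
#' each amplicon, from [select_top_cpgs()]).
#'
#' @param mat Methylation matrix tibble (see [fit_cpg_trajectories()]).
#' @param cpg_ids Character vector of CpG column names, or a tibble with
#'   a `cpg_id` column (e.g. the output of [select_top_cpgs()]).
#' @return A [clock_model] of kind `"multivariable-linear"`.
#' @export
train_multivariable <- function(mat, cpg_ids) {
  d <- clock_design(mat, cpg_ids)
  p <- ncol(d$X)
  if (length(d$age) <= p) {
    abort("Need more samples than CpGs to fit a multivariable clock.")
  }
  Xd <- cbind(`(Intercept)` = 1, d$X)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    aliased <- setdiff(colnames(Xd)[qrX$pivot[-seq_len(qrX$rank)]], "(Intercept)")
    abort(paste0("Design is rank deficient; collinear CpG column(s): ",
                 paste(aliased, collapse = ", ")))
  }
  beta <- qr.coef(qrX, d$age)
  new_clock_model(
    kind = "multivariable-linear",
    terms = tibble::tibble(cpg_id = colnames(d$X),
                           coefficient = unname(beta[-1L])),
    intercept = unname(beta[1L]),
    meta = list(n = length(d$age), n_dropped = d$n_dropped,
                seed = NULL, lambda = NULL, folds = NULL)
  )
}

#' Train a lasso clock with cross-validated penalty
#'
#' L1-penalized least squares of age on beta fractions over all (or the
#' given) CpG columns, via `glmnet` with `alpha = 1`. Predictors are
#' standardized internally and coefficients are reported on the original
#' beta-fraction scale. The penalty `lambda` is the minimizer of the
#' mean cross-validation error over a 100-value log-spaced grid running
#' from the smallest all-zero-coefficient lambda down by a factor 1e-4;
#' fold assignment is a deterministic shuffle under `seed`, recorded in
#' the model metadata. CpGs whose coefficient is shrunk exactly to zero
#' are dropped from the returned model.
#'
#' @inheritParams train_multivariable
#' @param cpg_ids CpG columns to offer to the lasso; default all.
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment (required).
#' @param lambda Optional explicit lambda grid (decreasing); overrides
#'   the automatic grid. The cross-validated minimizer is still used.
#' @return A [clock_model] of kind `"lasso"`.
#' @export
train_lasso <- function(mat, cpg_ids = NULL, n_folds = 10L, seed, lambda = NULL) {
  if (missing(seed)) abort("`seed` is required for reproducible fold assignment.")
  cpg_ids <- cpg_ids %||% cpg_cols(tibble::as_tibble(mat))
  d <- clock_design(mat, cpg_ids)
  n <- length(d$age)
  if (n < n_folds) {
    abort(sprintf("Only %d usable samples for %d folds; reduce `n_folds`.",
                  n, n_folds))
  }
  foldid <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  cv <- glmnet::cv.glmnet(d$X, d$age, alpha = 1, foldid = foldid,
                          nlambda = 100L, lambda.min.ratio = 1e-4,
                          lambda = lambda, standardize = TRUE,
                          thresh = 1e-10)
  co <- as.matrix(coef(cv, s = "lambda.min"))[, 1L]
  terms <- tibble::tibble(cpg_id = names(co)[-1L], coefficient = unname(co[-1L])) |>
    dplyr::filter(.data$coefficient != 0)
  new_clock_model(
    kind = "lasso",
    terms = terms,
    intercept = unname(co[1L]),
    meta = list(n = n, n_dropped = d$n_dropped, seed = as.integer(seed),
                lambda = cv$lambda.min, folds = as.integer(n_folds))
  )
}

#' Predict epigenetic age with a clock model
#'
#' Applies `intercept + sum(coef_j * beta_j)`. Predictions are not
#' clamped: negative or >200-week ages are reported as-is.
#'
#' @param model A [clock_model].
#' @param mat Methylation matrix tibble containing every CpG column the
#'   model uses (all values non-missing), or a named numeric vector of
#'   beta fractions for a single sample.
#' @return Tibble with `sample_id` (if present), `age_weeks` (if
#'   present) and `predicted_age_weeks`.
#' @export
predict_age <- function(model, mat) {
  stopifnot(inherits(model, "clock_model"))
  if (is.numeric(mat) && !is.null(names(mat))) {
    mat <- tibble::as_tibble(as.list(mat))
  }
  mat <- tibble::as_tibble(mat)
  need <- model$terms$cpg_id
  missing_cols <- setdiff(need, names(mat))
  if (length(missing_cols)) {
    abort(paste0("Model CpG(s) missing from input: ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(mat[, need, drop = FALSE])
  if (length(need) > 0L && anyNA(X)) {
    bad <- unique(colnames(X)[which(is.na(X), arr.ind = TRUE)[, 2L]])
    abort(paste0("Missing beta values in model CpG(s): ",
                 paste(bad, collapse = ", ")))
  }
  pred <- model$intercept +
    if (length(need)) drop(X %*% model$terms$coefficient) else 0
  out <- tibble::tibble(predicted_age_weeks = as.numeric(pred))
  for (col in c("age_weeks", "sample_id")) {
    if (col %in% names(mat)) out <- dplyr::bind_cols(mat[col], out)
  }
  out
}

#' Evaluate age predictions against chronological age
#'
#' Computes the statistics used to benchmark targeted clocks: R-squared
#' (headline value: squared Pearson correlation of predicted versus
#' chronological age; the identity-line variant `1 - SSres/SStot` is also
#' reported), and the median and mean absolute error in weeks.
#'
#' @param predicted Predicted ages in weeks, or a tibble with columns
#'   `predicted_age_weeks` and `age_weeks` (e.g. from [predict_age()]).
#' @param chronological Chronological ages in weeks (omit when
#'   `predicted` is a tibble).
#' @return A `clock_evaluation` object; see [tidy()] for per-sample
#'   errors and [glance()] for the summary row.
#' @examples
#' ev <- evaluate_clock(c(10, 20, 30), c(12, 25, 41))
#' glance(ev)$median_abs_error  # 5
#' @export
evaluate_clock <- function(predicted, chronological = NULL) {
  if (is.data.frame(predicted)) {
    chronological <- predicted$age_weeks
    predicted <- predicted$predicted_age_weeks
  }
  if (length(predicted) != length(chronological)) {
    abort("`predicted` and `chronological` must have equal length.")
  }
  if (length(predicted) < 2L) abort("Need at least 2 samples to evaluate.")
  abs_err <- abs(predicted - chronological)
  r <- safe_cor(predicted, chronological)
  ss_res <- sum((predicted - chronological)^2)
  ss_tot <- sum((chronological - mean(chronological))^2)
  structure(
    list(
      samples = tibble::tibble(predicted = predicted,
                               chronological = chronological,
                               abs_error = abs_err),
      r_squared = r^2,
      r_squared_identity = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      median_abs_error = median(abs_err),
      mean_abs_error = mean(abs_err)
    ),
    class = "clock_evaluation"
  )
}

#' @export
print.clock_evaluation <- function(x, ...) {
  cat(sprintf("<clock_evaluation> n = %d: R^2 = %.3f, median error = %.2f weeks, mean error = %.2f weeks\n",
              nrow(x$samples), x$r_squared, x$median_abs_error,
              x$mean_abs_error))
  invisible(x)
}

#' @describeIn evaluate_clock Per-sample predicted/chronological pairs
#'   and absolute errors.
#' @param x A `clock_evaluation`.
#' @param ... Unused.
#' @method tidy clock_evaluation
#' @export
tidy.clock_evaluation <- function(x, ...) x$samples

#' @describeIn evaluate_clock One-row summary: `n`, `r_squared`,
#'   `r_squared_identity`, `median_abs_error`, `mean_abs_error`.
#' @method glance clock_evaluation
#' @export
glance.clock_evaluation <- function(x, ...) {
  tibble::tibble(n = nrow(x$samples), r_squared = x$r_squared,
                 r_squared_identity = x$r_squared_identity,
                 median_abs_error = x$median_abs_error,
                 mean_abs_error = x$mean_abs_error)
}

#' Fit an age-acceleration trend
#'
#' Shorter-lived strains show epigenetic ages running ahead of
#' chronological age; the trend of predicted on chronological age is
#' summarized by least squares as either `a * age + b` (linear) or
#' `a * log(age) + b` (logarithmic, the shape seen for accelerated
#' strains).
#'
#' @param predicted Predicted ages in weeks.
#' @param chronological Chronological ages in weeks (strictly positive
#'   for the logarithmic form).
#' @param form `"linear"` or `"logarithmic"`.
#' @return One-row tibble: `form`, `a`, `b`, `r_squared` (squared
#'   Pearson correlation of fitted versus observed predictions).
#' @export
fit_acceleration <- function(predicted, chronological,
                             form = c("linear", "logarithmic")) {
  form <- match.arg(form)
  if (length(predicted) != length(chronological)) {
    abort("`predicted` and `chronological` must have equal length.")
  }
  if (form == "logarithmic" && any(chronological <= 0)) {
    abort("Logarithmic form requires strictly positive chronological ages.")
  }
  x <- if (form == "logarithmic") log(chronological) else chronological
  fit <- lm(predicted ~ x)
  fitted_vals <- unname(fitted(fit))
  r <- safe_cor(fitted_vals, predicted)
  tibble::tibble(form = form,
                 a = unname(coef(fit)[2L]),
                 b = unname(coef(fit)[1L]),
                 r_squared = if (is.na(r)) NA_real_ else r^2)
}
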