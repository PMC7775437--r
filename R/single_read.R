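#' Build a single-read age model for one amplicon
#'
#' Deep amplicon bisulfite sequencing yields, for every read, a binary
#' sequel of methylated and unmethylated CpGs. Under the observation that
#' age-associated methylation accrues stochastically and near
#' independently at neighboring CpGs, each read can be assigned its most
#' representative age: per-CpG linear DNAm-age trajectories fitted on a
#' training set give an expected methylation probability
#' `p_i(a) = clip(intercept_i + slope_i * a, epsilon, 1 - epsilon)` at
#' every age `a` of an integer grid (0 to 200 weeks), and a read's age is
#' the grid maximizer of the independent-Bernoulli log-likelihood of its
#' pattern.
#'
#' All CpGs of the amplicon are used (not only the top age-associated
#' ones); CpGs whose trajectory is undefined (zero variance) are excluded
#' with a message. Fewer than two usable CpGs is an error -- a
#' single-site pattern carries essentially no age signal.
#'
#' @param mat Training methylation matrix tibble (see
#'   [fit_cpg_trajectories()]); trajectories must be fit on training
#'   samples only.
#' @param amplicon Amplicon name whose CpG columns to use.
#' @param epsilon Probability clip in (0, 0.5); keeps every pattern at
#'   finite log-likelihood at every grid age. Default 0.01.
#' @return A `single_read_model`.
#' @export
single_read_model <- function(mat, amplicon, epsilon = 0.01) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      !is.finite(epsilon) || epsilon <= 0 || epsilon >= 0.5) {
    abort("`epsilon` must lie strictly between 0 and 0.5.")
  }
  traj <- fit_cpg_trajectories(mat) |>
    dplyr::filter(.data$amplicon == !!amplicon)
  if (nrow(traj) == 0L) abort(sprintf("No CpG columns for amplicon '%s'.", amplicon))
  usable <- !is.na(traj$pearson_r)
  if (any(!usable)) {
    message(sprintf("Excluding %d CpG(s) with undefined trajectories: %s",
                    sum(!usable),
                    paste(traj$cpg_id[!usable], collapse = ", ")))
  }
  traj <- traj[usable, ]
  if (nrow(traj) < 2L) {
    abort("Fewer than 2 usable CpGs; refusing to build a single-read model.")
  }
  new_single_read_model(amplicon, traj, epsilon)
}

new_single_read_model <- function(amplicon, trajectories, epsilon,
                                  age_grid = 0:200) {
  # precompute clipped Bernoulli probabilities: CpGs x grid ages
  P <- outer(trajectories$slope, age_grid) + trajectories$intercept
  P <- clip(P, epsilon, 1 - epsilon)
  structure(
    list(amplicon = amplicon,
         trajectories = tibble::as_tibble(trajectories),
         epsilon = epsilon,
         age_grid = age_grid,
         log_p = log(P),
         log_q = log1p(-P)),
    class = "single_read_model"
  )
}

#' @export
print.single_read_model <- function(x, ...) {
  cat(sprintf("<single_read_model> %s: %d CpGs, grid %d..%d weeks, epsilon %.3g\n",
              x$amplicon, nrow(x$trajectories), min(x$age_grid),
              max(x$age_grid), x$epsilon))
  invisible(x)
}

#' @describeIn single_read_model Per-CpG trajectory table of the model.
#' @param x A `single_read_model`.
#' @param ... Unused.
#' @method tidy single_read_model
#' @export
tidy.single_read_model <- function(x, ...) x$trajectories

#' Predict the epigenetic age of individual read patterns
#'
#' Assigns each binary methylation pattern its most representative age:
#' the grid age maximizing the independent-Bernoulli log-likelihood
#' `sum_i [x_i log p_i(a) + (1 - x_i) log(1 - p_i(a))]`, with missing
#' positions (`?`) dropping out of the sum. Ties are resolved to the
#' lowest age.
#'
#' @param model A [single_read_model()].
#' @param patterns Character vector of patterns over `0`/`1`/`?`, length
#'   matching the model's CpG count.
#' @return Numeric vector of ages in weeks (grid values, 0--200); `NA`
#'   for patterns with every position missing.
#' @examples
#' \dontrun{
#' predict_read_age(model, c("110?", "0000"))
#' }
#' @export
predict_read_age <- function(model, patterns) {
  stopifnot(inherits(model, "single_read_model"))
  X <- pattern_to_matrix(patterns)
  if (ncol(X) != nrow(model$trajectories)) {
    abort(sprintf("Pattern length %d does not match the model's %d CpGs.",
                  ncol(X), nrow(model$trajectories)))
  }
  seen <- !is.na(X)
  X1 <- ifelse(seen, X, 0L)          # methylated indicator, missing -> 0
  X0 <- ifelse(seen, 1L - X, 0L)     # unmethylated indicator, missing -> 0
  ll <- X1 %*% model$log_p + X0 %*% model$log_q   # reads x grid ages
  idx <- apply(ll, 1L, which.max)    # first maximum = lowest age on ties
  age <- model$age_grid[idx]
  age[rowSums(seen) == 0L] <- NA_real_
  as.numeric(age)
}

#' Predict a sample's age from its read patterns
#'
#' Predicts an age for every read via [predict_read_age()] and summarizes
#' the sample as the read-count-weighted mean of the single-read ages,
#' together with the full predicted-age frequency distribution over the
#' age grid (the per-sample row of the single-read heatmaps). Reads with
#' more than half of their CpG calls missing are excluded before
#' prediction, as near-empty patterns otherwise pile up at boundary ages.
#'
#' @param table Pattern table for one sample and one amplicon
#'   ([pattern_table()]).
#' @param model The matching [single_read_model()].
#' @return List with `mean_age` (weeks; `NA` with a warning if no read
#'   survives), `n_reads` (reads used) and `distribution`, a tibble
#'   (`sample_id`, `amplicon`, `age`, `frequency`) over the whole grid
#'   with frequencies summing to 1.
#' @export
predict_sample_age <- function(table, model) {
  stopifnot(inherits(model, "single_read_model"))
  table <- tibble::as_tibble(table)
  if (nrow(table) > 0L && any(table$amplicon != model$amplicon)) {
    abort(sprintf("Pattern table amplicon(s) %s do not match model amplicon '%s'.",
                  paste(unique(table$amplicon), collapse = ", "),
                  model$amplicon))
  }
  sample_id <- if (nrow(table)) table$sample_id[1L] else NA_character_
  grid <- model$age_grid
  empty_dist <- tibble::tibble(sample_id = sample_id,
                               amplicon = model$amplicon,
                               age = grid, frequency = NA_real_)
  if (nrow(table) == 0L) {
    warn("Empty pattern table: sample age undefined.")
    return(list(mean_age = NA_real_, n_reads = 0L, distribution = empty_dist))
  }
  k <- nrow(model$trajectories)
  n_missing <- nchar(gsub("[01]", "", table$pattern))
  keep <- n_missing <= k / 2
  table <- table[keep, , drop = FALSE]
  if (nrow(table) == 0L) {
    warn("All reads excluded (>50% missing calls): sample age undefined.")
    return(list(mean_age = NA_real_, n_reads = 0L, distribution = empty_dist))
  }
  ages <- predict_read_age(model, table$pattern)
  w <- as.numeric(table$count)
  mean_age <- sum(w * ages) / sum(w)
  freq <- vapply(grid, function(a) sum(w[ages == a]), 0) / sum(w)
  list(mean_age = mean_age,
       n_reads = as.integer(sum(w)),
       distribution = tibble::tibble(sample_id = sample_id,
                                     amplicon = model$amplicon,
                                     age = grid, frequency = freq))
}

#' Combine per-amplicon single-read age predictions
#'
#' The final single-read age of a sample is the (by default equally)
#' weighted mean of its per-amplicon mean single-read predictions;
#' amplicons with an undefined mean drop out, their weight redistributed.
#'
#' @param means Numeric vector of per-amplicon mean ages (may contain
#'   `NA`), or a data frame with columns `amplicon` and `mean_age`.
#' @param weights Optional non-negative weights, one per amplicon
#'   (default equal).
#' @return Single combined age in weeks (`NA` if no amplicon mean is
#'   defined).
#' @export
combine_amplicon_ages <- function(means, weights = NULL) {
  if (is.data.frame(means)) means <- setNames(means$mean_age, means$amplicon)
  means <- as.numeric(means)
  weights <- weights %||% rep(1, length(means))
  if (length(weights) != length(means)) {
    abort("`weights` must match `means` in length.")
  }
  if (any(weights < 0)) abort("`weights` must be non-negative.")
  ok <- is.finite(means) & weights > 0
  if (!any(ok)) {
    warn("No defined amplicon means to combine.")
    return(NA_real_)
  }
  sum(means[ok] * weights[ok]) / sum(weights[ok])
}
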