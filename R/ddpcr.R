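#' Percent methylation from ddPCR droplet counts by Poisson statistics
#'
#' In droplet digital PCR the reaction is partitioned into `n_droplets`
#' droplets and each droplet scores positive in a channel if it received
#' at least one target copy. With copies Poisson-distributed across
#' droplets, the mean copies per droplet in channel c is recovered from
#' the fraction of positive droplets as
#' `lambda_c = -log(1 - pos_c / N)`, and the percent methylation is
#' `100 * lambda_meth / (lambda_meth + lambda_unmeth)`. Double-positive
#' droplets are counted in both channels (per-channel counts, not
#' exclusive classes), which is what the per-channel Poisson formula
#' assumes.
#'
#' A 95% confidence interval is obtained by propagating the binomial
#' standard errors of the positive fractions through the log transform
#' and the ratio (delta method), truncated to \[0, 100\]. A channel with
#' all droplets positive is saturated: the Poisson estimate diverges, so
#' lambda is capped at `-log(1/(2N))` and the row is flagged
#' `saturated = TRUE`. If both channels have zero positives the percent
#' is undefined (`NA`, flagged `undefined = TRUE`).
#'
#' @param wells Data frame with one row per well: columns `n_droplets`,
#'   `pos_meth`, `pos_unmeth`; any other columns (e.g. `sample_id`,
#'   `target`) are carried through.
#' @return The input tibble plus columns `lambda_meth`, `lambda_unmeth`,
#'   `percent_meth`, `ci_low`, `ci_high`, `saturated`, `undefined`.
#' @examples
#' ddpcr_estimate(tibble::tibble(n_droplets = 10000,
#'                               pos_meth = 500, pos_unmeth = 1500))
#' @export
ddpcr_estimate <- function(wells) {
  wells <- tibble::as_tibble(wells)
  req <- c("n_droplets", "pos_meth", "pos_unmeth")
  miss <- setdiff(req, names(wells))
  if (length(miss)) abort(paste0("`wells` is missing columns: ",
                                 paste(miss, collapse = ", ")))
  N <- wells$n_droplets
  if (any(N <= 0)) abort("`n_droplets` must be positive.")
  if (any(wells$pos_meth < 0 | wells$pos_meth > N) ||
      any(wells$pos_unmeth < 0 | wells$pos_unmeth > N)) {
    abort("Positive-droplet counts must lie in [0, n_droplets].")
  }

  chan <- function(pos) {
    p <- pos / N
    sat <- pos == N
    lam <- ifelse(sat, -log(1 / (2 * N)), -log(1 - p))
    # delta method: Var(lambda) = Var(p) / (1-p)^2, Var(p) = p(1-p)/N
    se <- ifelse(sat, NA_real_, sqrt(p / (N * (1 - p))))
    list(lambda = lam, se = se, sat = sat)
  }
  m <- chan(wells$pos_meth)
  u <- chan(wells$pos_unmeth)
  saturated <- m$sat | u$sat
  if (any(saturated)) {
    warn(sprintf("%d well(s) saturated (all droplets positive in a channel); lambda capped at -log(1/(2N)).",
                 sum(saturated)))
  }
  tot <- m$lambda + u$lambda
  undefined <- tot == 0
  pct <- ifelse(undefined, NA_real_, 100 * m$lambda / tot)

  # delta method on R = lm/(lm+lu):
  # Var(R) = (lu^2 Var(lm) + lm^2 Var(lu)) / (lm+lu)^4
  se_pct <- 100 * sqrt((u$lambda^2 * m$se^2 + m$lambda^2 * u$se^2)) / tot^2
  z <- qnorm(0.975)
  ci_low <- clip(pct - z * se_pct, 0, 100)
  ci_high <- clip(pct + z * se_pct, 0, 100)

  dplyr::mutate(wells,
                lambda_meth = m$lambda, lambda_unmeth = u$lambda,
                percent_meth = pct,
                ci_low = ci_low, ci_high = ci_high,
                saturated = saturated, undefined = undefined)
}

#' Simulate a ddPCR well
#'
#' Generates droplet counts for a well with a known true percent
#' methylation: `total_copies` template molecules are split between the
#' methylated and unmethylated species according to `true_percent`, each
#' species is Poisson-distributed across the `n_droplets` droplets, and a
#' droplet is channel-positive iff it holds at least one copy of that
#' species (so the number of positives is Binomial(N, 1 - exp(-mu))).
#' Intended as the test oracle for [ddpcr_estimate()].
#'
#' @param true_percent True percent methylation in \[0, 100\].
#' @param total_copies Total template copies in the well.
#' @param n_droplets Number of droplets N.
#' @param seed Integer seed; the well is deterministic given the seed.
#' @return One-row tibble with `n_droplets`, `pos_meth`, `pos_unmeth` and
#'   the generating `true_percent`.
#' @export
ddpcr_simulate_well <- function(true_percent, total_copies, n_droplets, seed) {
  if (!is.finite(true_percent) || true_percent < 0 || true_percent > 100) {
    abort("`true_percent` must be in [0, 100].")
  }
  if (!is.finite(total_copies) || total_copies < 0) {
    abort("`total_copies` must be non-negative.")
  }
  n_droplets <- as.integer(n_droplets)
  if (n_droplets < 1L) abort("`n_droplets` must be positive.")
  mu_m <- total_copies * true_percent / 100 / n_droplets
  mu_u <- total_copies * (1 - true_percent / 100) / n_droplets
  with_seed(seed, {
    tibble::tibble(
      n_droplets = n_droplets,
      pos_meth = rbinom(1L, n_droplets, 1 - exp(-mu_m)),
      pos_unmeth = rbinom(1L, n_droplets, 1 - exp(-mu_u)),
      true_percent = true_percent
    )
  })
}
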