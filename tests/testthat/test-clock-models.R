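test_that("trajectory fits recover exact and hand-computed lines", {
  t1 <- fit_cpg_trajectory(c(0.10, 0.20, 0.30), c(0, 100, 200))
  expect_equal(t1$slope, 0.001)
  expect_equal(t1$intercept, 0.10)
  expect_equal(t1$pearson_r, 1)

  # hand normal equations: Sxy/Sxx = 15.8/8000 (fraction scale)
  t2 <- fit_cpg_trajectory(c(0.12, 0.25, 0.20, 0.40), c(10, 50, 90, 130))
  expect_equal(t2$slope, 0.001975)
  expect_equal(t2$intercept, 0.10425)
  expect_equal(t2$pearson_r, 0.8653, tolerance = 1e-4)
  expect_equal(t2$r_squared, t2$pearson_r^2)

  # degenerate: constant beta -> zero slope, undefined r
  t3 <- fit_cpg_trajectory(rep(0.5, 4), c(10, 50, 90, 130))
  expect_equal(t3$slope, 0)
  expect_true(is.na(t3$pearson_r))

  expect_error(fit_cpg_trajectory(c(0.1, 0.2), c(1, 2)), "3 samples")
  expect_error(fit_cpg_trajectory(c(0.1, 0.2, 0.3), c(5, 5, 5)), "equal")
})

test_that("top-CpG selection picks highest |r| per amplicon with a deterministic tie-break", {
  ages <- c(10, 40, 70, 100, 130)
  mat <- tibble::tibble(
    sample_id = paste0("s", 1:5), age_weeks = ages,
    `A:1` = 0.3 + 0.0001 * ages + c(0.05, -0.06, 0.02, -0.01, 0.01),
    `A:2` = 0.1 + 0.004 * ages,              # r = 1, the winner
    `B:1` = 0.2 + 0.002 * ages,
    `B:2` = 0.9 - 0.002 * ages               # |r| = 1 too, but higher index
  )
  top <- select_top_cpgs(mat, per_amplicon = 1)
  expect_equal(top$cpg_id, c("A:2", "B:1"))

  # exact |r| tie within an amplicon: lower index wins
  mat_tie <- tibble::tibble(
    sample_id = paste0("s", 1:5), age_weeks = ages,
    `C:1` = 0.2 + 0.003 * ages,
    `C:2` = 0.8 - 0.003 * ages
  )
  expect_equal(select_top_cpgs(mat_tie)$cpg_id, "C:1")

  # amplicon with undefined correlations is excluded with a warning
  mat_na <- dplyr::mutate(mat_tie, `D:1` = 0.5, `D:2` = 0.5)
  expect_warning(top_na <- select_top_cpgs(mat_na), "excluded")
  expect_false(any(top_na$amplicon == "D"))
})

test_that("multivariable clock inverts a noise-free generating model exactly", {
  mat <- exact_matrix()
  model <- train_multivariable(mat, c("Amp:1", "Amp:2", "Amp:3"))
  pred <- predict_age(model, mat)
  expect_equal(pred$predicted_age_weeks, mat$age_weeks, tolerance = 1e-9)

  # single-CpG clock is the inverse of the trajectory line
  m1 <- train_multivariable(mat, "Amp:1")
  expect_equal(m1$terms$coefficient, 1 / 0.004, tolerance = 1e-9)
  expect_equal(m1$intercept, -0.1 / 0.004, tolerance = 1e-9)

  # duplicate column: rank-deficiency error naming the culprit
  mat_dup <- dplyr::mutate(mat, `Amp:4` = .data$`Amp:1`)
  expect_error(train_multivariable(mat_dup, c("Amp:1", "Amp:4")),
               "rank deficient")
})

test_that("predict_age applies coefficients linearly and validates inputs", {
  model <- readclock:::new_clock_model(
    "multivariable-linear",
    tibble::tibble(cpg_id = c("X:1", "X:2", "X:3"),
                   coefficient = c(200, -100, 50)),
    intercept = 10, meta = list(n = 5))
  out <- predict_age(model, c(`X:1` = 0.2, `X:2` = 0.1, `X:3` = 0.4))
  expect_equal(out$predicted_age_weeks, 60)

  expect_error(predict_age(model, c(`X:1` = 0.2, `X:2` = 0.1)),
               "X:3")
  expect_error(
    predict_age(model, tibble::tibble(`X:1` = 0.2, `X:2` = NA_real_,
                                      `X:3` = 0.4)),
    "Missing beta")
})

test_that("lasso matches the OLS oracle at (near-)zero penalty", {
  set.seed(21)
  n <- 40; p <- 5
  X <- matrix(runif(n * p, 0.1, 0.9), n, p,
              dimnames = list(NULL, paste0("A:", 1:p)))
  beta <- c(120, -60, 40, 0, 80)
  age <- 20 + X %*% beta + rnorm(n, 0, 2)
  mat <- dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("s", 1:n), age_weeks = as.numeric(age)),
    tibble::as_tibble(X))
  model <- train_lasso(mat, seed = 99,
                       lambda = c(10, 1, 0.1, 0.01, 1e-8))
  ols <- qr.coef(qr(cbind(1, X)), age)
  b <- model_coef_vector(model, colnames(X))
  expect_equal(b, unname(ols[-1]), tolerance = 1e-4)
  expect_equal(model$intercept, unname(ols[1]), tolerance = 1e-3)
})

test_that("huge penalty shrinks the lasso to the mean training age", {
  mat <- exact_matrix()
  model <- suppressWarnings(
    train_lasso(mat, n_folds = 5, seed = 3, lambda = c(1e6, 9e5, 8e5)))
  expect_equal(nrow(model$terms), 0L)
  expect_equal(predict_age(model, mat)$predicted_age_weeks,
               rep(mean(mat$age_weeks), nrow(mat)))
})

test_that("lasso refuses fewer samples than folds and records its metadata", {
  mat <- exact_matrix()  # 5 samples
  expect_error(train_lasso(mat, n_folds = 10, seed = 1), "reduce `n_folds`")
  model <- suppressWarnings(train_lasso(mat, n_folds = 5, seed = 42))
  g <- glance(model)
  expect_equal(g$seed, 42L)
  expect_equal(g$cv_folds, 5L)
  expect_true(is.finite(g$lambda))
  # deterministic under the seed
  model2 <- suppressWarnings(train_lasso(mat, n_folds = 5, seed = 42))
  expect_equal(model$terms, model2$terms)
  expect_equal(model$intercept, model2$intercept)
})

test_that("evaluation reports squared-Pearson R2 and error quantiles", {
  ev <- evaluate_clock(c(10, 20, 30), c(12, 25, 41))
  g <- glance(ev)
  expect_equal(g$median_abs_error, 5)
  expect_equal(g$mean_abs_error, 6)

  perfect <- glance(evaluate_clock(c(5, 50, 100), c(5, 50, 100)))
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$median_abs_error, 0)

  # constant shift: correlation untouched, error equals the shift
  shift <- glance(evaluate_clock(c(5, 50, 100) + 7, c(5, 50, 100)))
  expect_equal(shift$r_squared, 1)
  expect_equal(shift$median_abs_error, 7)

  # swapping arguments preserves R2 but not the identity-line R2
  a <- c(12, 30, 55, 90); b <- c(10, 35, 50, 100)
  expect_equal(glance(evaluate_clock(a, b))$r_squared,
               glance(evaluate_clock(b, a))$r_squared)
  expect_equal(glance(evaluate_clock(a, b))$median_abs_error,
               glance(evaluate_clock(b, a))$median_abs_error)

  # zero variance -> flagged undefined
  expect_true(is.na(glance(evaluate_clock(rep(10, 3), c(1, 2, 3)))$r_squared))
})

test_that("tidy/glance methods follow broom conventions", {
  mat <- exact_matrix()
  model <- train_multivariable(mat, c("Amp:1", "Amp:2"))
  td <- tidy(model)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$term[1], "(Intercept)")
  expect_s3_class(glance(model), "tbl_df")
  expect_equal(nrow(glance(model)), 1L)
})

test_that("acceleration fits recover linear and logarithmic trends", {
  ages <- seq(5, 120, length.out = 30)
  lin <- fit_acceleration(ages, ages, form = "linear")
  expect_equal(lin$a, 1, tolerance = 1e-12)
  expect_equal(lin$b, 0, tolerance = 1e-9)

  pred_log <- 30 * log(ages) + 5
  logfit <- fit_acceleration(pred_log, ages, form = "logarithmic")
  expect_equal(logfit$a, 30, tolerance = 1e-6)
  expect_equal(logfit$b, 5, tolerance = 1e-6)
  expect_equal(logfit$r_squared, 1, tolerance = 1e-9)

  flat <- fit_acceleration(rep(50, 10), seq(1, 10), form = "linear")
  expect_equal(flat$a, 0)

  expect_error(fit_acceleration(c(1, 2), c(0, 10), form = "logarithmic"),
               "positive")
})

test_that("fitted slopes track generating slopes on a simulated cohort", {
  # parameter recovery: strongly age-associated CpGs within +/-20%
  panel <- sim_panel()
  co <- simulate_cohort(panel, n_mice = 24, reads_per_amplicon = 500,
                        seed = 1234)
  mat <- methylation_matrix(co$patterns, co$samples)
  fits <- fit_cpg_trajectories(mat)
  gen <- tidy(panel)
  joined <- dplyr::inner_join(fits, gen, by = "cpg_id",
                              suffix = c("_fit", "_gen"))
  strong <- dplyr::filter(joined, abs(.data$pearson_r) > 0.8)
  expect_gt(nrow(strong), 5)
  expect_true(all(abs(strong$slope_fit / strong$slope_gen - 1) < 0.2))
})
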