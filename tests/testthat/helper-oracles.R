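# Independent oracles used to cross-check package computations.
# These deliberately re-derive results by brute force / first principles
# and share no code with the implementation paths they check.

# exhaustive grid evaluation of the single-read log-likelihood; ties to
# the lowest age. `traj` has columns slope, intercept.
oracle_read_age <- function(pattern, traj, epsilon, age_grid = 0:200) {
  x <- strsplit(pattern, "")[[1]]
  best_age <- NA_real_
  best_ll <- -Inf
  for (a in age_grid) {
    ll <- 0
    any_seen <- FALSE
    for (i in seq_along(x)) {
      if (x[i] == "?") next
      any_seen <- TRUE
      p <- traj$intercept[i] + traj$slope[i] * a
      p <- min(max(p, epsilon), 1 - epsilon)
      ll <- ll + if (x[i] == "1") log(p) else log(1 - p)
    }
    if (!any_seen) return(NA_real_)
    if (ll > best_ll) {  # strict: first (lowest) age wins ties
      best_ll <- ll
      best_age <- a
    }
  }
  best_age
}

# per-read loop computing per-CpG methylation means (beta) from a
# pattern table, expanding each pattern by its count
oracle_betas <- function(table) {
  k <- nchar(table$pattern[1])
  meth <- numeric(k)
  seen <- numeric(k)
  for (r in seq_len(nrow(table))) {
    x <- strsplit(table$pattern[r], "")[[1]]
    for (rep in seq_len(table$count[r])) {
      for (i in seq_len(k)) {
        if (x[i] == "?") next
        seen[i] <- seen[i] + 1
        meth[i] <- meth[i] + (x[i] == "1")
      }
    }
  }
  ifelse(seen > 0, meth / seen, NA_real_)
}

# glmnet-convention lasso objective for coefficients on the original
# scale: (1/2n)||y - b0 - Xb||^2 + lambda * sum(s_j |b_j|), with the
# intercept profiled out and s_j the biased (1/n) column sd
lasso_objective <- function(X, y, b, lambda) {
  n <- length(y)
  s <- apply(X, 2, function(col) sqrt(mean((col - mean(col))^2)))
  b0 <- mean(y - X %*% b)
  rss <- sum((y - b0 - X %*% b)^2)
  rss / (2 * n) + lambda * sum(s * abs(b))
}

# FISTA proximal-gradient solver for the same objective, run in the
# standardized space and mapped back to the original scale
oracle_lasso <- function(X, y, lambda, iters = 20000) {
  n <- nrow(X)
  mx <- colMeans(X)
  s <- apply(X, 2, function(col) sqrt(mean((col - mean(col))^2)))
  keep <- s > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mx[keep]), 2, s[keep], "/")
  yc <- y - mean(y)
  p <- ncol(Xs)
  L <- max(eigen(crossprod(Xs) / n, symmetric = TRUE,
                 only.values = TRUE)$values)
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  b <- rep(0, p); z <- b; tk <- 1
  for (it in seq_len(iters)) {
    grad <- crossprod(Xs, Xs %*% z - yc) / n
    b_new <- soft(z - grad / L, lambda / L)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- b_new + ((tk - 1) / t_new) * (b_new - b)
    if (max(abs(b_new - b)) < 1e-12 && it > 10) { b <- b_new; break }
    b <- b_new; tk <- t_new
  }
  out <- rep(0, ncol(X))
  out[keep] <- b / s[keep]
  out
}

# full coefficient vector of a clock model over the given CpG columns
model_coef_vector <- function(model, cpg_ids) {
  b <- setNames(rep(0, length(cpg_ids)), cpg_ids)
  b[model$terms$cpg_id] <- model$terms$coefficient
  unname(b)
}
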