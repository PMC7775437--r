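#  small shared helpers (no exports)

# clip into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed so package randomness never perturbs user code
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Pearson r that returns NA (instead of erroring/NaN-warning) on zero
# variance in either argument
safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

stopifnot_scalar_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1].", name))
  }
  invisible(x)
}

# split pattern strings ("1?0...") into an integer matrix with NA for '?'
pattern_to_matrix <- function(patterns) {
  if (length(patterns) == 0L) {
    return(matrix(integer(), nrow = 0L, ncol = 0L))
  }
  n <- unique(nchar(patterns))
  if (length(n) != 1L) abort("All patterns must have the same length.")
  chars <- matrix(unlist(strsplit(patterns, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(patterns), ncol = n, byrow = TRUE)
  bad <- !chars %in% c("0", "1", "?")
  if (any(bad)) abort("Patterns may only contain '0', '1' and '?'.")
  out <- matrix(NA_integer_, nrow = nrow(chars), ncol = n)
  out[chars == "1"] <- 1L
  out[chars == "0"] <- 0L
  out
}

matrix_to_pattern <- function(m) {
  chars <- matrix("?", nrow = nrow(m), ncol = ncol(m))
  chars[!is.na(m) & m == 1L] <- "1"
  chars[!is.na(m) & m == 0L] <- "0"
  apply(chars, 1L, paste0, collapse = "")
}
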