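# Internal helpers shared across modules.

# Round half away from zero (printed tables use half-up, not banker's).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code under a fixed RNG seed without disturbing the caller's stream.
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Truncated-normal draws on (lo, hi) by inverse-CDF; sd = 0 degenerates to
# the mean (clamped). Uses exactly n uniforms so draw counts are stable.
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  u <- runif(n)
  if (sd <= 0) {
    return(rep(min(max(mean, lo), hi), n))
  }
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
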