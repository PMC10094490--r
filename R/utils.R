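# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific RNG seed from a master seed
#'
#' Keeps every stochastic stage independently seeded while remaining a pure
#' function of the master seed, so whole runs are reproducible end to end.
#'
#' @param seed master integer seed.
#' @param stage small non-negative integer identifying the stage.
#' @return an integer seed below 2^31.
#' @keywords internal
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + as.numeric(stage) * 99991) %% 2147483647)
}

# Negative-binomial draws parameterized by mean and dispersion alpha
# (variance = mu + alpha * mu^2); alpha ~ 0 degenerates to Poisson.
rnbinom_mu <- function(n, mu, alpha) {
  if (alpha <= 1e-12) {
    stats::rpois(n, lambda = mu)
  } else {
    stats::rnbinom(n, mu = mu, size = 1 / alpha)
  }
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("'%s' must be a single number", name)
  }
  if (x < min || x > max) {
    stopf("'%s' must be in [%s, %s], got %s", name, min, max, x)
  }
  invisible(x)
}

# Deterministic numeric formatting for text outputs (independent of options()).
fmt_num <- function(x, digits = 6) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}
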