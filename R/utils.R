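# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded package functions do not
#' disturb the caller's random stream. `seed = NULL` leaves the stream alone.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive k child seeds from one master seed, each < 2^31.
spawn_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, k)))
}

# expm1(z)/z with the z -> 0 limit handled.
relexpm1 <- function(z) {
  out <- ifelse(abs(z) < 1e-8, 1 + z / 2, expm1(z) / z)
  out
}

# Akaike weights from a vector of AICc values (NA entries excluded).
aicc_weights <- function(aicc) {
  w <- rep(NA_real_, length(aicc))
  ok <- is.finite(aicc)
  if (any(ok)) {
    d <- aicc[ok] - min(aicc[ok])
    ew <- exp(-d / 2)
    w[ok] <- ew / sum(ew)
  }
  w
}

aicc_value <- function(lnL, k, n_obs) {
  if (n_obs - k - 1 <= 0) {
    stop("AICc undefined: need n_obs > k + 1 (n_obs = ", n_obs, ", k = ", k, ")")
  }
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

# Equal-tail percentile interval (type 7 quantiles).
percentile_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, probs = c(a, 1 - a), names = FALSE, na.rm = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
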