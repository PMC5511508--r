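# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' All randomness in a pipeline run flows from a single integer seed; each
#' stage draws from its own substream so that adding a stage never perturbs
#' the draws of another.
#'
#' @param seed integer master seed.
#' @param stream character stream name (e.g. `"cohort"`, `"contours"`).
#' @return an integer seed < 2^31.
#' @keywords internal
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

#' Moments of a truncated normal distribution
#'
#' Mean and standard deviation of N(mu, sd^2) restricted to (lo, hi),
#' by the standard Mills-ratio formulas.
#'
#' @param mu,sd mean and SD of the parent normal (sd > 0).
#' @param lo,hi truncation bounds (either may be infinite).
#' @return named numeric vector `c(mean =, sd =)`.
#' @export
truncnorm_moments <- function(mu, sd, lo = -Inf, hi = Inf) {
  stopifnot(sd > 0, lo < hi)
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  if (Z <= 0) stop("empty truncation region")
  da <- dnorm(a); db <- dnorm(b)
  am <- if (is.finite(a)) a * da else 0
  bm <- if (is.finite(b)) b * db else 0
  m <- mu + sd * (da - db) / Z
  v <- sd^2 * (1 + (am - bm) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Sample from a truncated normal by inverse-CDF
#'
#' @param n number of draws.
#' @param mu,sd parent normal parameters.
#' @param lo,hi truncation bounds.
#' @return numeric vector of length `n` inside (lo, hi).
#' @keywords internal
rtruncnorm <- function(n, mu, sd, lo = -Inf, hi = Inf) {
  pa <- pnorm(lo, mu, sd)
  pb <- pnorm(hi, mu, sd)
  qnorm(pa + runif(n) * (pb - pa), mu, sd)
}
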