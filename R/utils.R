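# Internal helpers shared across modules: seeded evaluation, rolling window
# arithmetic, truncated-normal sampling.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under an explicit RNG seed
#'
#' All stochastic operations in this package require an explicit integer
#' seed; calling them without one is an error.  The global RNG state is
#' saved and restored so simulations do not perturb the caller's stream.
#'
#' @param seed single finite integer-valued seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  check_seed(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

check_seed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed))
    stopf("an explicit integer 'seed' is required for stochastic operations")
  invisible(as.integer(seed))
}

# Rolling sum over trailing windows of length k; result[i] is the sum of
# x[(i-k+1):i], NA for i < k.
roll_sum <- function(x, k) {
  n <- length(x)
  if (k > n) return(rep(NA_real_, n))
  cs <- cumsum(c(0, x))
  out <- rep(NA_real_, n)
  out[k:n] <- cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]
  out
}

# Population standard deviation over trailing windows of length k.
roll_sd_pop <- function(x, k) {
  s1 <- roll_sum(x, k)
  s2 <- roll_sum(x^2, k)
  v <- pmax(s2 / k - (s1 / k)^2, 0)
  sqrt(v)
}

# TRUE where every element of the trailing window of length k is TRUE.
roll_all <- function(flag, k) {
  s <- roll_sum(as.numeric(flag), k)
  out <- s >= k
  out[is.na(out)] <- FALSE
  out
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Truncated normal draws via inverse-CDF (vectorised, exact bounds).
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lower), upper))
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, pl, pu)
  stats::qnorm(u, mean, sd)
}

# Mean of a normal(mu, sd) truncated to [lower, upper].
tnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# Draw n values from a normal truncated to [lower, upper] whose location is
# shifted so the *truncated distribution's* mean equals target_mean.  A
# truncated normal's mean is not its location parameter, so generators that
# must realize a stated mean inside a bounded window solve for the location
# numerically.
rtnorm_target_mean <- function(n, target_mean, sd, lower, upper) {
  if (target_mean <= lower || target_mean >= upper)
    stopf("target mean %.3f outside truncation window [%g, %g]",
          target_mean, lower, upper)
  f <- function(mu) tnorm_mean(mu, sd, lower, upper) - target_mean
  mu <- stats::uniroot(f, lower = lower - 6 * sd, upper = upper + 6 * sd,
                       tol = 1e-10)$root
  x <- rtnorm(n, mu, sd, lower, upper)
  # remove residual sampling error of the sample mean; the shift is small
  # so re-clipping to the window is a negligible perturbation
  pmin(pmax(x + (target_mean - mean(x)), lower), upper)
}

# Shift/rescale a sample to an exact mean and (population) sd.
standardize_to <- function(x, mean_target, sd_target) {
  s <- pop_sd(x)
  if (s == 0) return(rep(mean_target, length(x)))
  mean_target + (x - mean(x)) / s * sd_target
}
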