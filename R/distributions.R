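# Emission-distribution helpers: gamma moment parameterization and the
# wrapped Cauchy circular distribution.

#' Convert a gamma mean/sd to shape/rate
#'
#' Priors are placed on the mean and standard deviation of the step-length
#' distribution; the density itself needs shape and rate.
#'
#' @param mean,sd Positive gamma mean and standard deviation.
#' @return List with `shape = mean^2/sd^2` and `rate = mean/sd^2`.
#' @export
gamma_shape_rate <- function(mean, sd) {
  if (any(mean <= 0) || any(sd <= 0)) stop("mean and sd must be positive")
  list(shape = mean^2 / sd^2, rate = mean / sd^2)
}

#' Wrapped-Cauchy log density
#'
#' `f(theta) = (1 - rho^2) / (2 pi (1 + rho^2 - 2 rho cos(theta - mu)))` on
#' the circle; `rho = 0` is the circular uniform.
#'
#' @param theta Angle(s), radians.
#' @param mu Mean direction, radians.
#' @param rho Concentration in `[0, 1)`.
#' @return Log density, vectorized over `theta`.
#' @export
wrapped_cauchy_logpdf <- function(theta, mu, rho) {
  if (any(rho < 0) || any(rho >= 1)) stop("rho must lie in [0, 1)")
  log1p(-rho^2) - log(2 * pi) - log1p(rho^2 - 2 * rho * cos(theta - mu))
}

#' Draw wrapped-Cauchy variates
#'
#' Samples a Cauchy with scale `-log(rho)` and wraps it to `(-pi, pi]`;
#' `rho = 0` falls back to the circular uniform. Uses R's RNG stream.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param rho Concentration in `[0, 1)`; may be length `n` for per-draw values.
#' @return `n` angles in `(-pi, pi]`.
#' @export
rwrapped_cauchy <- function(n, mu, rho) {
  if (any(rho < 0) || any(rho >= 1)) stop("rho must lie in [0, 1)")
  u <- stats::runif(n)
  rho <- rep_len(rho, n)
  mu <- rep_len(mu, n)
  theta <- ifelse(rho == 0,
                  mu + 2 * pi * (u - 0.5),
                  mu - log(rho) * tan(pi * (u - 0.5)))
  wrap_angle(theta)
}
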