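# Convergence diagnostics and posterior summaries.

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance ratio:
#' `Rhat = sqrt(((n-1)/n * W + (1 + 1/m) * B/n) / W)` with `m` chains of `n`
#' draws each.
#'
#' For circular parameters (turning-angle means), the statistic is computed
#' on angular deviations from the pooled circular mean: a posterior
#' concentrated at the +/-pi wrap point would otherwise split its draws
#' across the discontinuity and inflate the diagnostic without any actual
#' convergence failure.
#'
#' @param samples A `posterior_samples` (>= 2 chains).
#' @param parameter Column name of `samples$draws`.
#' @param circular Treat the parameter as an angle on `(-pi, pi]`.
#' @return Scalar PSRF (>= 1 up to floating error).
#' @export
gelman_rubin <- function(samples, parameter, circular = FALSE) {
  x <- samples$draws[, parameter]
  if (circular)
    x <- wrap_angle(x - atan2(mean(sin(x)), mean(cos(x))))
  ch <- samples$chain
  m <- length(unique(ch))
  if (m < 2L) stop("Gelman-Rubin needs at least 2 chains")
  n <- min(table(ch))
  if (n < 10L) stop("need at least 10 draws per chain")
  grp <- split(x, ch)
  means <- vapply(grp, mean, numeric(1))
  vars <- vapply(grp, stats::var, numeric(1))
  W <- mean(vars)
  B_over_n <- stats::var(means)          # = B/n
  if (W == 0) return(1)
  vhat <- (n - 1) / n * W + (1 + 1 / m) * B_over_n
  sqrt(vhat / W)
}

#' All PSRFs of a posterior sample
#' @param samples A `posterior_samples`.
#' @return Named vector of PSRFs, one per (non-derived) parameter column;
#'   turning-angle means are treated as circular.
#' @export
gelman_rubin_all <- function(samples) {
  vapply(colnames(samples$draws), function(p)
    gelman_rubin(samples, p, circular = p %in% c("mu_turn1", "mu_turn2")),
    numeric(1))
}

#' Highest posterior density interval (empirical, Chen-Shao)
#'
#' Scans contiguous windows of the sorted draws and returns the narrowest
#' interval `(x[i], x[i + ceiling(mass * n)])`; ties take the lowest start.
#'
#' @param draws Numeric vector (>= 20 draws).
#' @param mass Interval mass in (0, 1); default 0.90.
#' @return Numeric `c(lo, hi)`.
#' @export
hpdi <- function(draws, mass = 0.90) {
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  n <- length(draws)
  if (n < 20L) stop("need at least 20 draws for an HPDI")
  x <- sort(draws)
  gap <- ceiling(mass * n)
  if (gap >= n) return(c(x[1L], x[n]))
  lo_i <- seq_len(n - gap)
  width <- x[lo_i + gap] - x[lo_i]
  i <- which.min(width)                   # which.min takes the first minimum
  c(x[i], x[i + gap])
}

#' Posterior medians and 90% HPDIs for all parameters and derived quantities
#'
#' Derived rows: the state-2 step mean `mu2_step = mu1_step + delta` and the
#' `(cos, sin)` components of each turning-angle mean (per-draw, then
#' summarized).
#'
#' @param samples A `posterior_samples`.
#' @param mass HPDI mass, default 0.90.
#' @return data.frame with columns `parameter`, `median`, `lo`, `hi`.
#' @export
summarize_posterior <- function(samples, mass = 0.90) {
  d <- samples$draws
  derived <- cbind(
    mu2_step = d[, "mu1_step"] + d[, "delta"],
    cos_mu_turn1 = cos(d[, "mu_turn1"]), sin_mu_turn1 = sin(d[, "mu_turn1"]),
    cos_mu_turn2 = cos(d[, "mu_turn2"]), sin_mu_turn2 = sin(d[, "mu_turn2"]))
  all <- cbind(d, derived)
  ints <- apply(all, 2, hpdi, mass = mass)
  data.frame(parameter = colnames(all),
             median = apply(all, 2, stats::median),
             lo = ints[1L, ], hi = ints[2L, ], row.names = NULL)
}

#' Write posterior draws / summaries to CSV
#' @param samples A `posterior_samples`.
#' @param path Output path.
#' @export
write_draws <- function(samples, path) {
  utils::write.csv(data.frame(chain = samples$chain, samples$draws,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
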