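# Shared fixtures and independent oracles. Everything here is deliberately
# naive (direct formulas, exhaustive enumeration) and independent of the
# package's computational path.

basis5 <- build_basis(make_knots(5, 1, 365))

# direct wrapped-Cauchy density, straight from the formula
wc_pdf <- function(theta, mu, rho) {
  (1 - rho^2) / (2 * pi * (1 + rho^2 - 2 * rho * cos(theta - mu)))
}

# random valid model parameters over `start_days`
random_params <- function(start_days = 1L, K = 5L) {
  emissions <- emission_params(
    mu1_step = runif(1, 0.3, 2), delta = runif(1, 1, 8),
    sd_step = runif(2, 0.3, 5), mu_turn = runif(2, -pi, pi),
    rho_turn = runif(2, 0, 0.9))
  transitions <- transition_params(
    beta0 = rnorm(2, -2, 1), b = matrix(rnorm(2 * K, 0, 0.5), K, 2),
    sigma_b = runif(2, 0.2, 2))
  initial <- initial_state_params(
    setNames(runif(length(start_days)), start_days))
  hmm_params(emissions, transitions, initial)
}

# random short series with missingness, as a complete daily grid
random_series <- function(T, start_day = sample(1:300, 1), p_miss = 0.3) {
  step <- runif(T, 0.05, 10)
  turn <- runif(T, -pi + 1e-9, pi)
  miss <- runif(T) < p_miss
  step[miss] <- NA
  turn[miss | c(TRUE, runif(T - 1) < p_miss)] <- NA
  turn[1L] <- NA
  daily_step_series(start_day:(start_day + T - 1L), step, turn)
}

# exhaustive-path log likelihood for T <= ~12; emission densities from
# dgamma() and the direct wrapped-Cauchy formula
brute_force_loglik <- function(series, params, basis) {
  T <- nrow(series)
  ep <- params$emissions
  sr <- gamma_shape_rate(ep$mu_step, ep$sd_step)
  emis <- function(t, s) {
    ld <- 0
    if (!is.na(series$step_km[t]))
      ld <- ld + dgamma(series$step_km[t], shape = sr$shape[s],
                        rate = sr$rate[s], log = TRUE)
    if (!is.na(series$turn_rad[t]))
      ld <- ld + log(wc_pdf(series$turn_rad[t], ep$mu_turn[s],
                            ep$rho_turn[s]))
    ld
  }
  phi1 <- params$initial$phi1[[as.character(attr(series, "start_day"))]]
  paths <- as.matrix(expand.grid(rep(list(1:2), T)))
  lp <- apply(paths, 1, function(s) {
    l <- log(c(phi1, 1 - phi1)[s[1L]]) + emis(1L, s[1L])
    for (t in seq_len(T)[-1L]) {
      G <- transition_matrix(series$day[t], params$transitions, basis)
      l <- l + log(G[s[t - 1L], s[t]]) + emis(t, s[t])
    }
    l
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# exhaustive-path Viterbi argmax (ties: first row of expand.grid order is
# all-ones, and which.max picks the first maximum, matching ties-to-state-1)
brute_force_viterbi <- function(series, params, basis) {
  T <- nrow(series)
  ep <- params$emissions
  sr <- gamma_shape_rate(ep$mu_step, ep$sd_step)
  emis <- function(t, s) {
    ld <- 0
    if (!is.na(series$step_km[t]))
      ld <- ld + dgamma(series$step_km[t], shape = sr$shape[s],
                        rate = sr$rate[s], log = TRUE)
    if (!is.na(series$turn_rad[t]))
      ld <- ld + log(wc_pdf(series$turn_rad[t], ep$mu_turn[s],
                            ep$rho_turn[s]))
    ld
  }
  phi1 <- params$initial$phi1[[as.character(attr(series, "start_day"))]]
  paths <- as.matrix(expand.grid(rep(list(1:2), T)))
  lp <- apply(paths, 1, function(s) {
    l <- log(c(phi1, 1 - phi1)[s[1L]]) + emis(1L, s[1L])
    for (t in seq_len(T)[-1L]) {
      G <- transition_matrix(series$day[t], params$transitions, basis)
      l <- l + log(G[s[t - 1L], s[t]]) + emis(t, s[t])
    }
    l
  })
  paths[which.max(lp), ]
}

# minimal posterior_samples-shaped object for diagnostic/summary tests
fake_samples <- function(draws, chain) {
  structure(list(draws = draws, chain = chain), class = "posterior_samples")
}
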