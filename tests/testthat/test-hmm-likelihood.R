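test_that("daily transition matrices follow the logit-spline form and are stochastic", {
  b <- basis5
  p0 <- transition_params(c(0, 0), matrix(0, 5, 2), c(1, 1))
  expect_equal(transition_matrix(100, p0, b),
               matrix(0.5, 2, 2))
  # strongly negative intercept saturates row 1 toward staying put
  psat <- transition_params(c(-30, 0), matrix(0, 5, 2), c(1, 1))
  expect_equal(transition_matrix(100, psat, b)[1, ], c(1, 0), tolerance = 1e-12)

  set.seed(21)
  for (i in 1:25) {
    tp <- transition_params(rnorm(2), matrix(rnorm(10), 5, 2), runif(2, .1, 2))
    d <- sample(365, 1)
    G <- transition_matrix(d, tp, b)
    # entries match the direct scalar logit computation
    expect_equal(G[1, 2], plogis(tp$beta0[1] + sum(tp$b[, 1] * b$Z[d, ])))
    expect_equal(G[2, 1], plogis(tp$beta0[2] + sum(tp$b[, 2] * b$Z[d, ])))
    expect_equal(rowSums(G), c(1, 1))
  }
  expect_error(transition_matrix(0, p0, b), "1..365")
  expect_error(transition_matrix(366, p0, b), "1..365")
})

test_that("emission log density marginalizes missing components", {
  set.seed(31)
  ep <- emission_params(0.7, 5, c(0.5, 4), c(pi, 0), c(0.3, 0.7))
  expect_equal(emission_logdensity(NA, NA, 1, ep), 0)
  expect_equal(emission_logdensity(NA, NA, 2, ep), 0)
  sr <- gamma_shape_rate(0.7, 0.5)
  expect_equal(emission_logdensity(1.2, NA, 1, ep),
               dgamma(1.2, sr$shape, sr$rate, log = TRUE))
  for (i in 1:20) {
    s <- runif(1, .01, 12); th <- runif(1, -pi, pi); st <- sample(2, 1)
    srs <- gamma_shape_rate(ep$mu_step[st], ep$sd_step[st])
    expect_equal(emission_logdensity(s, th, st, ep),
                 dgamma(s, srs$shape, srs$rate, log = TRUE) +
                   log(wc_pdf(th, ep$mu_turn[st], ep$rho_turn[st])))
  }
  expect_error(emission_logdensity(-1, NA, 1, ep), "positive")
})

test_that("forward log likelihood equals exhaustive path enumeration", {
  set.seed(41)
  for (i in 1:60) {
    T <- sample(2:8, 1)
    start_day <- sample(1:300, 1)
    params <- random_params(start_days = start_day)
    s <- random_series(T, start_day = start_day)
    ll <- forward_loglik(s, params, basis5)
    bf <- brute_force_loglik(s, params, basis5)
    expect_equal(ll, bf, tolerance = 1e-10)
  }
})

test_that("a single all-missing day has log likelihood zero", {
  params <- random_params(start_days = 50L)
  s <- daily_step_series(50L, NA_real_, NA_real_)
  expect_equal(forward_loglik(s, params, basis5), 0)
})

test_that("likelihood over multiple series is the sum of per-series terms", {
  set.seed(43)
  params <- random_params(start_days = c(10L, 20L))
  s1 <- random_series(6, 10L); s2 <- random_series(5, 20L)
  expect_equal(forward_loglik(list(s1, s2), params, basis5),
               forward_loglik(s1, params, basis5) +
                 forward_loglik(s2, params, basis5))
})

test_that("the forward recursion is invariant to relabeling states", {
  # swap emission columns, transpose the switch probabilities and flip the
  # initial distribution: the marginal likelihood cannot change
  set.seed(47)
  for (i in 1:10) {
    T <- 30L
    ld <- matrix(rnorm(2 * T), T, 2)
    g12 <- runif(365, 0, .5); g21 <- runif(365, 0, .5)
    phi1 <- runif(1)
    a <- seasonhmm:::forward_cpp(ld, 0L, T, 100L, phi1, g12, g21)
    b <- seasonhmm:::forward_cpp(ld[, 2:1], 0L, T, 100L, 1 - phi1, g21, g12)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("Viterbi decoding matches the exhaustive argmax and transition-only limits", {
  set.seed(53)
  for (i in 1:25) {
    T <- sample(3:8, 1)
    start_day <- sample(1:300, 1)
    params <- random_params(start_days = start_day)
    s <- random_series(T, start_day = start_day)
    expect_equal(viterbi_decode(s, params, basis5),
                 unname(brute_force_viterbi(s, params, basis5)))
  }
  # near-identical emissions: the path is driven by the transition model,
  # which here overwhelmingly favors staying in state 1
  ep <- emission_params(1, 1e-9, c(1, 1), c(0, 0), c(0.2, 0.2))
  tp <- transition_params(c(-8, 8), matrix(0, 5, 2), c(1, 1))
  params <- hmm_params(ep, tp, initial_state_params(c("100" = 0.999)))
  s <- daily_step_series(100:119, c(NA, runif(19, .5, 2)),
                         c(NA, NA, runif(18, -3, 3)))
  expect_equal(viterbi_decode(s, params, basis5), rep(1L, 20L))
})

test_that("state decoding on simulated deer-like tracks is highly accurate", {
  set.seed(59)
  sc <- preset_scenario("deer_like", n_animal_years = 5)
  sim <- simulate_scenario(sc)
  vt <- viterbi_decode(sim$series, sc$params, sc$basis)
  obs <- lapply(sim$series, function(s) !is.na(s$step_km))
  acc <- mean(unlist(Map(function(v, st, o) (v == st)[o],
                         vt, sim$states, obs)))
  expect_gt(acc, 0.9)
})

test_that("model parameters survive a YAML round trip", {
  set.seed(61)
  params <- random_params(start_days = c(1L, 7L))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_hmm_params(params, path)
  back <- read_hmm_params(path)
  expect_equal(back$emissions, params$emissions, tolerance = 1e-8)
  expect_equal(back$transitions, params$transitions, tolerance = 1e-8)
  expect_equal(back$initial$phi1, params$initial$phi1, tolerance = 1e-8,
               ignore_attr = TRUE)
})
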