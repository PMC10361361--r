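test_that("log prior returns -Inf outside support instead of erroring", {
  params <- random_params(start_days = 1L)
  bad <- params
  bad$emissions$rho_turn[2] <- 1.2
  expect_identical(log_prior(bad), -Inf)
  bad <- params
  bad$emissions$delta <- -0.5
  expect_identical(log_prior(bad), -Inf)
  bad <- params
  bad$transitions$sigma_b[1] <- 0
  expect_identical(log_prior(bad), -Inf)
})

test_that("log prior equals the independently summed per-term densities", {
  set.seed(71)
  halfnorm <- function(x, s) dnorm(x, 0, s, log = TRUE) + log(2)
  for (i in 1:20) {
    p <- random_params(start_days = c(1L, 4L))
    ep <- p$emissions; tp <- p$transitions
    manual <- halfnorm(ep$mu1_step, 10) + halfnorm(ep$delta, 10) +
      halfnorm(ep$sd_step[1], 10) + halfnorm(ep$sd_step[2], 10) +
      dunif(ep$mu_turn[1], -pi, pi, log = TRUE) +
      dunif(ep$mu_turn[2], -pi, pi, log = TRUE) +
      dnorm(tp$beta0[1], 0, 2, log = TRUE) +
      dnorm(tp$beta0[2], 0, 2, log = TRUE) +
      halfnorm(tp$sigma_b[1], 10) + halfnorm(tp$sigma_b[2], 10) +
      sum(dnorm(tp$b[, 1], 0, tp$sigma_b[1], log = TRUE)) +
      sum(dnorm(tp$b[, 2], 0, tp$sigma_b[2], log = TRUE))
    # rho ~ U(0,1) and phi ~ Dirichlet(1,1) add zero
    expect_equal(log_prior(p), manual)
  }
})

test_that("empirical HPDI finds the narrowest window with lowest-start ties", {
  expect_equal(hpdi(1:100, 0.90), c(1, 91))
  expect_equal(hpdi(rep(3.5, 25), 0.90), c(3.5, 3.5))
  set.seed(73)
  x <- rnorm(2e4)
  int <- hpdi(x, 0.90)
  # symmetric unimodal: interval roughly symmetric about 0
  expect_equal(int[1], -int[2], tolerance = 0.1)
  expect_equal(unname(diff(int)), 2 * qnorm(0.95), tolerance = 0.05)
  expect_error(hpdi(1:100, 1.2), "mass")
  expect_error(hpdi(1:5, 0.9), "at least 20")
})

test_that("Gelman-Rubin matches an aov-based reference and flags separation", {
  set.seed(79)
  m <- 4L; n <- 500L
  x <- rnorm(m * n, mean = rep(c(0, .1, -.1, .05), each = n))
  s <- fake_samples(cbind(par = x), rep(1:m, each = n))
  # independent route: between/within mean squares from a one-way anova
  ms <- anova(lm(x ~ factor(rep(1:m, each = n))))[["Mean Sq"]]
  W <- ms[2]; B_over_n <- ms[1] / n
  ref <- sqrt(((n - 1) / n * W + (1 + 1 / m) * B_over_n) / W)
  expect_equal(gelman_rubin(s, "par"), ref, tolerance = 1e-10)

  ident <- fake_samples(cbind(par = rep(rnorm(n), 2)), rep(1:2, each = n))
  expect_equal(gelman_rubin(ident, "par"), 1, tolerance = 1e-2)

  sep <- fake_samples(cbind(par = c(rnorm(n), rnorm(n, 10))),
                      rep(1:2, each = n))
  expect_gt(gelman_rubin(sep, "par"), 3)
  expect_error(gelman_rubin(fake_samples(cbind(par = rnorm(n)), rep(1, n)),
                            "par"), "2 chains")
})

test_that("Gelman-Rubin agrees with coda on shared input", {
  skip_if_not_installed("coda")
  set.seed(83)
  m <- 3L; n <- 4000L
  x <- rnorm(m * n)
  s <- fake_samples(cbind(par = x), rep(1:m, each = n))
  cd <- coda::gelman.diag(coda::mcmc.list(lapply(split(x, rep(1:m, each = n)),
                                                 coda::mcmc)),
                          autoburnin = FALSE)$psrf[1, 1]
  # coda applies a d.f. correction absent from the classic ratio; at this
  # sample size the two agree closely
  expect_equal(gelman_rubin(s, "par"), unname(cd), tolerance = 2e-3)
})

test_that("posterior summaries expose medians, HPDIs and derived rows", {
  set.seed(89)
  draws <- cbind(mu1_step = rgamma(200, 20, 20), delta = rgamma(200, 9, 3),
                 mu_turn1 = runif(200, -pi, pi), mu_turn2 = rnorm(200, 0, .2),
                 const = rep(2, 200))
  s <- fake_samples(draws, rep(1:2, each = 100))
  out <- summarize_posterior(s)
  expect_equal(out$median[out$parameter == "const"], 2)
  expect_equal(out$lo[out$parameter == "const"], 2)
  expect_equal(out$median, apply(cbind(draws,
                                       mu2_step = draws[, 1] + draws[, 2],
                                       cos_mu_turn1 = cos(draws[, 3]),
                                       sin_mu_turn1 = sin(draws[, 3]),
                                       cos_mu_turn2 = cos(draws[, 4]),
                                       sin_mu_turn2 = sin(draws[, 4])),
                                 2, median),
               ignore_attr = TRUE)
  expect_gt(out$median[out$parameter == "mu2_step"],
            out$median[out$parameter == "mu1_step"])
})

test_that("the sampler is draw-for-draw reproducible under a fixed seed", {
  set.seed(97)
  sc <- preset_scenario("deer_like", n_animal_years = 2)
  sim <- simulate_scenario(sc)
  cfg <- sampler_config(n_chains = 2, n_iter = 300, n_burn = 100, thin = 2,
                        seed = 5)
  p1 <- sample_posterior(sim$series, config = cfg, basis = sc$basis)
  p2 <- sample_posterior(sim$series, config = cfg, basis = sc$basis)
  expect_identical(p1$draws, p2$draws)
  # retained draw count: chains x (n_iter - n_burn) / thin
  expect_equal(nrow(p1$draws), 2 * (300 - 100) / 2)
  # label constraint holds in every draw
  expect_true(all(p1$draws[, "delta"] > 0))
})

test_that("sampler configurations round-trip through YAML", {
  cfg <- sampler_config(4L, 8000L, 3000L, 2L, seed = 77L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sampler_config(cfg, path)
  expect_equal(read_sampler_config(path), cfg)
})

test_that("with uninformative data the sampler reproduces the prior", {
  # every observation missing => the likelihood is identically 1, so the
  # draws must follow the prior; this exercises every transform and
  # Jacobian in the sampler
  s <- daily_step_series(1:8, rep(NA_real_, 8), rep(NA_real_, 8))
  cfg <- sampler_config(n_chains = 2, n_iter = 20000, n_burn = 2000, thin = 2,
                        seed = 19)
  post <- suppressWarnings(sample_posterior(list(s), config = cfg))
  d <- post$draws
  # half-normal(10) marginals: median 10 * qnorm(0.75) = 6.745
  expect_lt(abs(median(d[, "mu1_step"]) - 10 * qnorm(0.75)), 0.7)
  expect_lt(abs(median(d[, "delta"]) - 10 * qnorm(0.75)), 0.7)
  # intercepts ~ Normal(0, 2)
  expect_lt(abs(mean(d[, "beta0_12"])), 0.3)
  expect_lt(abs(sd(d[, "beta0_12"]) - 2), 0.25)
  # concentrations and initial-state probabilities uniform on (0, 1)
  expect_lt(abs(mean(d[, "rho_turn1"]) - 0.5), 0.06)
  expect_lt(abs(mean(d[, "phi1_d1"]) - 0.5), 0.06)
  expect_lt(abs(unname(quantile(d[, "rho_turn2"], 0.25)) - 0.25), 0.06)
})

test_that("degenerate single-state data pull the step-mean offset toward zero", {
  # all steps from one gamma, no state structure: delta has nothing to fit
  # and its posterior should concentrate far below its prior (median 6.7)
  set.seed(103)
  mk <- function() {
    T <- 200L
    daily_step_series(1:T, c(NA, rgamma(T - 1, shape = 4, rate = 4)),
                      c(NA, NA, runif(T - 2, -pi + 1e-9, pi)))
  }
  cfg <- sampler_config(n_chains = 2, n_iter = 1500, n_burn = 700, thin = 2,
                        seed = 23)
  post <- sample_posterior(list(mk(), mk()), config = cfg)
  expect_lt(median(post$draws[, "delta"]), 2)
})

test_that("doubling the chain length leaves posterior medians in place", {
  set.seed(157)
  sc <- preset_scenario("deer_like", n_animal_years = 5)
  sim <- simulate_scenario(sc)
  short <- sample_posterior(sim$series, basis = sc$basis,
                            config = sampler_config(3, 1500, 750, 5, seed = 29))
  long <- sample_posterior(sim$series, basis = sc$basis,
                           config = sampler_config(3, 3000, 750, 5, seed = 29))
  for (p in c("mu1_step", "delta", "sd_step1", "sd_step2",
              "rho_turn1", "rho_turn2")) {
    scale <- sd(long$draws[, p])
    expect_lt(abs(median(short$draws[, p]) - median(long$draws[, p])),
              4 * scale / sqrt(10))      # ~MC error of a thinned median
  }
})

test_that("90% HPDIs cover the emission truth at roughly nominal rate", {
  # scaled-down replicate study: small data sets and short chains keep the
  # run tractable; coverage should still sit near 90% per parameter
  sc <- preset_scenario("deer_like", n_animal_years = 15)
  truth <- c(mu1_step = 0.66, delta = 7.12 - 0.66, sd_step1 = 0.57,
             sd_step2 = 6.49, rho_turn1 = 0.26, rho_turn2 = 0.70)
  n_rep <- 8L
  covered <- matrix(NA, n_rep, length(truth),
                    dimnames = list(NULL, names(truth)))
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    sim <- simulate_scenario(sc)
    post <- sample_posterior(sim$series, basis = sc$basis,
                             config = sampler_config(3, 1200, 600, 3,
                                                     seed = 2000 + r))
    for (p in names(truth)) {
      int <- hpdi(post$draws[, p], 0.90)
      covered[r, p] <- truth[p] >= int[1] && truth[p] <= int[2]
    }
  }
  expect_gte(mean(covered), 0.8)
  expect_true(all(colSums(covered) >= 5L))
})
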