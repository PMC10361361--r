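# Posterior sampling for the seasonal two-state HMM.
#
# The latent states are marginalized by the forward algorithm, so the
# sampler only ever sees the continuous parameter vector. Sampling scale:
# positive parameters (step mean/SDs, delta, sigma_b) on the log scale,
# concentrations and initial-state probabilities on the logit scale, turning
# angle means wrapped modulo 2pi, everything else unconstrained; priors are
# applied on the natural scale with the corresponding Jacobian terms.
#
# Updates are blocked adaptive random-walk Metropolis:
#   * emission block (8 params): recomputes emission densities + forward pass
#   * two transition blocks (intercept + K spline coefficients each):
#     reuse cached emission densities, recompute the forward pass
#   * sigma_b scalars: prior-only (they never enter the likelihood)
#   * one logit-phi scalar per record-start day: forward pass only over the
#     series starting that day
# Each block's multivariate-normal proposal covariance is adapted during
# burn-in (empirical covariance scaled by 2.38^2/d, with a Robbins-Monro
# global-scale correction toward standard acceptance targets) and frozen at
# the end of burn-in so retained draws come from a fixed-kernel Markov chain.

#' MCMC sampler configuration
#'
#' Defaults reproduce the full-scale design: three chains of 20,000
#' iterations, 10,000 burn-in, thinning by 5, so 6,000 retained draws.
#'
#' @param n_chains Number of independent chains.
#' @param n_iter Iterations per chain.
#' @param n_burn Burn-in iterations discarded (must be `< n_iter`).
#' @param thin Thinning interval (>= 1).
#' @param seed Integer seed; the whole run is reproducible given it.
#' @param algorithm Tag recorded on the output.
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 3L, n_iter = 20000L, n_burn = 10000L,
                           thin = 5L, seed = 1L,
                           algorithm = "adaptive-blocked-rwm") {
  stopifnot(n_chains >= 1L, n_burn < n_iter, thin >= 1L)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 seed = as.integer(seed), algorithm = algorithm),
            class = "sampler_config")
}

#' Write / read a sampler configuration as YAML
#' @param config A `sampler_config`.
#' @param path File path.
#' @export
write_sampler_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sampler_config
#' @return `read_sampler_config()` returns the reconstructed
#'   `sampler_config`.
#' @export
read_sampler_config <- function(path) {
  x <- yaml::read_yaml(path)
  sampler_config(x$n_chains, x$n_iter, x$n_burn, x$thin, x$seed, x$algorithm)
}

# ---- internal machinery -----------------------------------------------------

.par_layout <- function(K, start_days) {
  n_phi <- length(start_days)
  nm <- c("mu1_step", "delta", "sd_step1", "sd_step2", "mu_turn1", "mu_turn2",
          "rho_turn1", "rho_turn2", "beta0_12", paste0("b12_", seq_len(K)),
          "beta0_21", paste0("b21_", seq_len(K)), "sigma_b1", "sigma_b2",
          if (n_phi) paste0("phi1_d", start_days))
  list(K = K, names = nm, n = length(nm),
       i_emis = 1:8, i_b12 = 9L + seq_len(K), i_b21 = 10L + K + seq_len(K),
       i_beta12 = 9L, i_beta21 = 10L + K,
       i_sig = c(11L + 2L * K, 12L + 2L * K),
       i_phi = if (n_phi) 12L + 2L * K + seq_len(n_phi) else integer(0),
       start_days = start_days)
}

# z[5:6] hold turning-angle means as offsets from a per-run reference
# direction (lay$mu_ref): the posterior then lives near 0 instead of at the
# +/-pi wrap, which would otherwise corrupt the adapted proposal covariance
.z_to_nat <- function(z, lay) {
  sigma_b <- exp(z[lay$i_sig])
  # non-centered spline coefficients: z holds u = b / sigma_b (u ~ N(0,1) a
  # priori), which decouples the coefficients from their hierarchical SD and
  # avoids the funnel when the seasonal signal is weak
  list(mu1 = exp(z[1L]), delta = exp(z[2L]), sd = exp(z[3:4]),
       mut = wrap_angle(lay$mu_ref + z[5:6]), rho = stats::plogis(z[7:8]),
       beta0 = z[c(lay$i_beta12, lay$i_beta21)],
       u = cbind(z[lay$i_b12], z[lay$i_b21]),
       b = cbind(z[lay$i_b12] * sigma_b[1L], z[lay$i_b21] * sigma_b[2L]),
       sigma_b = sigma_b,
       phi1 = stats::plogis(z[lay$i_phi]))
}

# log prior of the natural parameters + log Jacobian of the sampling
# transform; must agree with log_prior() on the shared terms (tested).
.lp_z <- function(z, nat, lay, priors) {
  if (any(nat$mut <= -pi | nat$mut > pi)) return(-Inf)
  lp <- .lhalfnorm(nat$mu1, priors$sd_mu1) +
    .lhalfnorm(nat$delta, priors$sd_delta) +
    sum(.lhalfnorm(nat$sd, priors$sd_sd_step)) +
    2 * (-log(2 * pi)) +
    sum(stats::dnorm(nat$beta0, 0, priors$sd_beta0, log = TRUE)) +
    sum(.lhalfnorm(nat$sigma_b, priors$sd_sigma_b)) +
    sum(stats::dnorm(nat$u, 0, 1, log = TRUE))
  jac <- sum(z[c(1:4, lay$i_sig)]) +
    sum(log(nat$rho) + log1p(-nat$rho)) +
    sum(log(nat$phi1) + log1p(-nat$phi1))
  lp + jac
}

.forward_all <- function(stk, ld, tg, phi1_series) {
  forward_cpp(ld, stk$start, stk$len, stk$start_day, phi1_series,
              tg$g12, tg$g21)
}

# adaptive proposal state for one block
.new_block <- function(idx, init_sd, target) {
  d <- length(idx)
  list(idx = idx, d = d, target = target, log_lambda = 0,
       mean = numeric(d), cov = diag(init_sd^2, d), n_ad = 0L,
       chol = diag(init_sd, d), n_acc = 0L, n_try = 0L)
}

.block_propose <- function(blk, z) {
  z[blk$idx] <- z[blk$idx] +
    exp(blk$log_lambda) * drop(stats::rnorm(blk$d) %*% blk$chol)
  z
}

.block_adapt <- function(blk, z, acc_prob, iter) {
  g <- 1 / max(iter, 10)^0.6
  blk$log_lambda <- blk$log_lambda + g * (acc_prob - blk$target)
  x <- z[blk$idx]
  blk$n_ad <- blk$n_ad + 1L
  dlt <- x - blk$mean
  blk$mean <- blk$mean + dlt / blk$n_ad
  blk$cov <- blk$cov + (tcrossprod(dlt, x - blk$mean) - blk$cov) / blk$n_ad
  if (blk$n_ad > 50L && blk$n_ad %% 25L == 0L) {
    sig <- (2.38^2 / blk$d) * (blk$cov + diag(1e-8, blk$d))
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (!is.null(ch)) blk$chol <- ch
  }
  blk
}

# starting values from a 2-group split of the observed step lengths
# (k-means; falls back to a 75th-percentile split if degenerate), so every
# chain starts in the basin where state 2 has the larger steps
.init_values <- function(stk, lay) {
  s <- stk$step[!is.na(stk$step)]
  if (length(s) < 10L) {                   # (nearly) no data: generic start
    z <- numeric(lay$n)
    z[1:4] <- log(c(1, 2, 1, 2))
    z[7:8] <- stats::qlogis(0.3)
    z[c(lay$i_beta12, lay$i_beta21)] <- stats::qlogis(0.1)
    return(z)
  }
  km <- tryCatch(stats::kmeans(s, centers = 2L, nstart = 3L),
                 error = function(e) NULL)
  if (!is.null(km) && length(unique(km$cluster)) == 2L) {
    hi_cl <- which.max(km$centers)
    lo <- s[km$cluster != hi_cl]; hi <- s[km$cluster == hi_cl]
    q <- max(lo)
  } else {
    q <- stats::quantile(s, 0.75, names = FALSE)
    lo <- s[s <= q]; hi <- s[s > q]
  }
  mu1 <- mean(lo); mu2 <- max(mean(hi), mu1 * 1.5)
  sd1 <- max(stats::sd(lo), 1e-3); sd2 <- max(stats::sd(hi), 1e-3)
  split_turn <- function(sel) {
    th <- stk$turn[sel]; th <- th[!is.na(th)]
    if (length(th) < 5L) return(c(0, 0.3))
    r <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)   # resultant length ~ rho
    c(atan2(mean(sin(th)), mean(cos(th))), min(max(r, 0.05), 0.9))
  }
  w1 <- split_turn(!is.na(stk$step) & stk$step <= q)
  w2 <- split_turn(!is.na(stk$step) & stk$step > q)
  z <- numeric(lay$n)
  z[1L] <- log(mu1); z[2L] <- log(mu2 - mu1)
  z[3:4] <- log(c(sd1, sd2))
  z[5:6] <- c(w1[1L], w2[1L])
  z[7:8] <- stats::qlogis(c(w1[2L], w2[2L]))
  z[c(lay$i_beta12, lay$i_beta21)] <- stats::qlogis(0.1)
  z[lay$i_sig] <- 0
  z[lay$i_phi] <- 0
  z
}

.run_chain <- function(stk, lay, priors, basis, config, chain_id, z0,
                       phi_series_map) {
  n_keep <- (config$n_iter - config$n_burn) %/% config$thin
  draws <- matrix(NA_real_, n_keep, lay$n)
  K <- lay$K

  blocks <- list(
    step = .new_block(1:4, 0.01, 0.234),
    turn = .new_block(5:8, 0.05, 0.234),
    t12 = .new_block(c(lay$i_beta12, lay$i_b12, lay$i_sig[1L]), 0.05, 0.234),
    t21 = .new_block(c(lay$i_beta21, lay$i_b21, lay$i_sig[2L]), 0.05, 0.234))
  # interweaved centered-scale moves for the coefficient SDs: with b held
  # fixed the likelihood is untouched, so these scalar updates are free and
  # break the u--sigma ridge the non-centered blocks crawl along
  asis <- list(s1 = .new_block(lay$i_sig[1L], 0.3, 0.44),
               s2 = .new_block(lay$i_sig[2L], 0.3, 0.44))
  phi_blocks <- lapply(lay$i_phi, .new_block, init_sd = 0.5, target = 0.44)

  # current state caches
  z <- z0
  nat <- .z_to_nat(z, lay)
  sr <- gamma_shape_rate(c(nat$mu1, nat$mu1 + nat$delta), nat$sd)
  ld <- emission_logdens_cpp(stk$step, stk$turn, sr$shape, sr$rate,
                             nat$mut, nat$rho)
  tg <- list(g12 = stats::plogis(nat$beta0[1L] + drop(basis$Z %*% nat$b[, 1L])),
             g21 = stats::plogis(nat$beta0[2L] + drop(basis$Z %*% nat$b[, 2L])))
  phi_series <- nat$phi1[phi_series_map]
  ll_s <- .forward_all(stk, ld, tg, phi_series)
  lp <- .lp_z(z, nat, lay, priors)
  if (!is.finite(lp + sum(ll_s))) stop("non-finite initial log posterior")

  adapting <- TRUE
  for (iter in seq_len(config$n_iter)) {
    if (iter > config$n_burn) adapting <- FALSE

    # emission blocks recompute densities + a full forward pass; transition
    # blocks reuse the cached densities and are cheap, so they get several
    # sweeps per iteration to keep the seasonal curves mixing
    for (bn in c("step", "turn", rep(c("t12", "t21"), 4L))) {
      blk <- blocks[[bn]]
      zp <- .block_propose(blk, z)
      natp <- .z_to_nat(zp, lay)
      lpp <- .lp_z(zp, natp, lay, priors)
      acc_prob <- 0
      if (is.finite(lpp)) {
        if (bn %in% c("step", "turn")) {
          srp <- gamma_shape_rate(c(natp$mu1, natp$mu1 + natp$delta), natp$sd)
          ldp <- emission_logdens_cpp(stk$step, stk$turn, srp$shape, srp$rate,
                                      natp$mut, natp$rho)
          llp <- .forward_all(stk, ldp, tg, phi_series)
        } else if (bn %in% c("t12", "t21")) {
          tgp <- list(
            g12 = stats::plogis(natp$beta0[1L] + drop(basis$Z %*% natp$b[, 1L])),
            g21 = stats::plogis(natp$beta0[2L] + drop(basis$Z %*% natp$b[, 2L])))
          llp <- .forward_all(stk, ld, tgp, phi_series)
        }
        lr <- (lpp + sum(llp)) - (lp + sum(ll_s))
        # a numerically pathological proposal (NaN likelihood) is rejected
        acc_prob <- if (is.nan(lr)) 0 else min(1, exp(lr))
        if (stats::runif(1) < acc_prob) {
          z <- zp; nat <- natp; lp <- lpp; ll_s <- llp
          if (bn %in% c("step", "turn")) ld <- ldp
          if (bn %in% c("t12", "t21")) tg <- tgp
          blk$n_acc <- blk$n_acc + 1L
        }
      }
      blk$n_try <- blk$n_try + 1L
      if (adapting) blk <- .block_adapt(blk, z, acc_prob, iter)
      blocks[[bn]] <- blk
    }

    # centered-scale sigma_b interweaving: propose log sigma with the
    # natural coefficients b = u * sigma fixed (u rescaled on accept)
    for (aj in 1:2) {
      blk <- asis[[aj]]
      isig <- lay$i_sig[aj]
      iu <- if (aj == 1L) lay$i_b12 else lay$i_b21
      sig <- exp(z[isig])
      b_nat <- z[iu] * sig
      lsig_p <- stats::rnorm(1, z[isig], exp(blk$log_lambda) * blk$chol[1L])
      sig_p <- exp(lsig_p)
      tgt <- function(s_, ls_)
        .lhalfnorm(s_, priors$sd_sigma_b) +
          sum(stats::dnorm(b_nat, 0, s_, log = TRUE)) + ls_
      lr <- tgt(sig_p, lsig_p) - tgt(sig, z[isig])
      acc_prob <- min(1, exp(lr))
      if (stats::runif(1) < acc_prob) {
        z[isig] <- lsig_p
        z[iu] <- b_nat / sig_p
        nat <- .z_to_nat(z, lay)
        lp <- .lp_z(z, nat, lay, priors)
        blk$n_acc <- blk$n_acc + 1L
      }
      blk$n_try <- blk$n_try + 1L
      if (adapting) {
        g <- 1 / max(iter, 10)^0.6
        blk$log_lambda <- blk$log_lambda + g * (acc_prob - blk$target)
      }
      asis[[aj]] <- blk
    }

    # one logit-phi scalar per record-start day
    for (pi_ in seq_along(phi_blocks)) {
      blk <- phi_blocks[[pi_]]
      sel <- which(phi_series_map == pi_)
      zp <- .block_propose(blk, z)
      natp <- .z_to_nat(zp, lay)
      lpp <- .lp_z(zp, natp, lay, priors)
      acc_prob <- 0
      if (is.finite(lpp)) {
        llp_sel <- forward_cpp(ld, stk$start[sel], stk$len[sel],
                               stk$start_day[sel], rep(natp$phi1[pi_],
                                                       length(sel)),
                               tg$g12, tg$g21)
        lr <- (lpp + sum(llp_sel)) - (lp + sum(ll_s[sel]))
        acc_prob <- if (is.nan(lr)) 0 else min(1, exp(lr))
        if (stats::runif(1) < acc_prob) {
          z <- zp; nat <- natp; lp <- lpp
          ll_s[sel] <- llp_sel
          phi_series[sel] <- natp$phi1[pi_]
          blk$n_acc <- blk$n_acc + 1L
        }
      }
      blk$n_try <- blk$n_try + 1L
      if (adapting) blk <- .block_adapt(blk, z, acc_prob, iter)
      phi_blocks[[pi_]] <- blk
    }

    if (iter > config$n_burn && (iter - config$n_burn) %% config$thin == 0L) {
      row <- (iter - config$n_burn) %/% config$thin
      draws[row, ] <- c(nat$mu1, nat$delta, nat$sd, nat$mut, nat$rho,
                        nat$beta0[1L], nat$b[, 1L], nat$beta0[2L],
                        nat$b[, 2L], nat$sigma_b, nat$phi1)
    }
  }

  acc <- vapply(c(blocks, phi_blocks),
                function(b) b$n_acc / max(b$n_try, 1L), numeric(1))
  names(acc) <- c(names(blocks), paste0("phi_d", lay$start_days))
  list(draws = draws, accept = acc)
}

#' Sample the posterior of the seasonal HMM
#'
#' All animal-year series are completely pooled: the target is
#' `log_prior + sum over series of forward_loglik`. See the package source
#' header of this file for the update scheme; the retained draws per chain
#' are `(n_iter - n_burn) / thin`.
#'
#' @param data A `daily_step_series` or list of them.
#' @param priors A `prior_spec`.
#' @param config A `sampler_config`.
#' @param basis A `spline_basis`; default is the K = 5 radial basis on
#'   evenly spaced knots over days 1..365.
#' @param init Optional list of starting `z` vectors (internal scale), one
#'   per chain; by default a moment split of the observed step lengths plus
#'   per-chain jitter.
#' @param max_init_retries Re-draws of jittered starts allowed before
#'   erroring when the initial log posterior is non-finite.
#' @return Object of class `posterior_samples`: `draws` (matrix, natural
#'   scale, named columns), `chain` (integer per draw), `accept` (per-chain
#'   block acceptance rates), `config`, `basis`, `start_days`.
#' @export
sample_posterior <- function(data, priors = prior_spec(),
                             config = sampler_config(),
                             basis = build_basis(make_knots(5, 1, 365)),
                             init = NULL, max_init_retries = 20L) {
  stk <- .stack_series(data)
  if (length(stk$len) == 0L) stop("need at least one series")
  start_days <- sort(unique(stk$start_day))
  phi_series_map <- match(stk$start_day, start_days)
  lay <- .par_layout(ncol(basis$Z), start_days)

  set.seed(config$seed)
  z_base <- .init_values(stk, lay)
  lay$mu_ref <- z_base[5:6]
  z_base[5:6] <- 0
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    z0 <- if (!is.null(init)) init[[ch]] else NULL
    tries <- 0L
    repeat {
      if (is.null(z0)) z0 <- z_base + stats::rnorm(lay$n, 0, 0.05)
      ok <- tryCatch({
        nat0 <- .z_to_nat(z0, lay)
        is.finite(.lp_z(z0, nat0, lay, priors))
      }, error = function(e) FALSE)
      if (ok) break
      z0 <- NULL
      tries <- tries + 1L
      if (tries > max_init_retries)
        stop("could not find a finite initial log posterior")
    }
    chains[[ch]] <- .run_chain(stk, lay, priors, basis, config, ch, z0,
                               phi_series_map)
  }

  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(draws) <- lay$names
  n_keep <- nrow(chains[[1L]]$draws)
  structure(list(draws = draws,
                 chain = rep(seq_len(config$n_chains), each = n_keep),
                 accept = lapply(chains, `[[`, "accept"),
                 config = config, basis = basis, start_days = start_days),
            class = "posterior_samples")
}

#' Rebuild an `hmm_params` from one posterior draw
#'
#' @param samples A `posterior_samples`.
#' @param i Draw (row) index.
#' @return The corresponding `hmm_params`.
#' @export
draw_params <- function(samples, i) {
  x <- samples$draws[i, ]
  K <- ncol(samples$basis$Z)
  hmm_params(
    emission_params(x[["mu1_step"]], x[["delta"]],
                    c(x[["sd_step1"]], x[["sd_step2"]]),
                    c(x[["mu_turn1"]], x[["mu_turn2"]]),
                    c(x[["rho_turn1"]], x[["rho_turn2"]])),
    transition_params(c(x[["beta0_12"]], x[["beta0_21"]]),
                      cbind(x[paste0("b12_", seq_len(K))],
                            x[paste0("b21_", seq_len(K))]),
                      c(x[["sigma_b1"]], x[["sigma_b2"]])),
    initial_state_params(stats::setNames(
      x[paste0("phi1_d", samples$start_days)], samples$start_days)))
}
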