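# Prior specification and joint log prior.
#
# All scale-like parameters (step mean/SDs, delta, spline-coefficient SDs)
# get half-normal priors (normal truncated at 0); turning-angle means and
# concentrations are uniform on their supports; logit-scale transition
# intercepts are Normal(0, 2); spline coefficients are hierarchically
# Normal(0, sigma_b); initial-state probabilities are Dirichlet(1, 1).

#' Prior hyperparameters
#'
#' Defaults follow the diffuse choices the model was designed around; all are
#' fixed constants.
#'
#' @param sd_mu1,sd_delta,sd_sd_step,sd_sigma_b Half-normal scale
#'   hyperparameters (default 10).
#' @param sd_beta0 Normal SD of the transition intercepts (default 2).
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(sd_mu1 = 10, sd_delta = 10, sd_sd_step = 10,
                       sd_beta0 = 2, sd_sigma_b = 10) {
  structure(list(sd_mu1 = sd_mu1, sd_delta = sd_delta,
                 sd_sd_step = sd_sd_step, sd_beta0 = sd_beta0,
                 sd_sigma_b = sd_sigma_b), class = "prior_spec")
}

.lhalfnorm <- function(x, sd) {
  ifelse(x > 0, stats::dnorm(x, 0, sd, log = TRUE) + log(2), -Inf)
}

#' Joint log prior density
#'
#' Parameters outside their support yield `-Inf` rather than an error, so the
#' function can sit directly inside an MCMC target.
#'
#' @param params An `hmm_params`.
#' @param priors A `prior_spec`.
#' @return Scalar log density (possibly `-Inf`).
#' @export
log_prior <- function(params, priors = prior_spec()) {
  ep <- params$emissions; tp <- params$transitions; phi1 <- params$initial$phi1
  if (any(ep$rho_turn < 0 | ep$rho_turn >= 1)) return(-Inf)
  if (any(ep$mu_turn <= -pi | ep$mu_turn > pi)) return(-Inf)
  if (ep$mu1_step <= 0 || ep$delta <= 0 || any(ep$sd_step <= 0)) return(-Inf)
  if (any(tp$sigma_b <= 0)) return(-Inf)
  if (any(phi1 < 0 | phi1 > 1)) return(-Inf)
  lp <- .lhalfnorm(ep$mu1_step, priors$sd_mu1) +
    .lhalfnorm(ep$delta, priors$sd_delta) +
    sum(.lhalfnorm(ep$sd_step, priors$sd_sd_step)) +
    2 * (-log(2 * pi)) +                       # uniform turning-angle means
    sum(stats::dnorm(tp$beta0, 0, priors$sd_beta0, log = TRUE)) +
    sum(.lhalfnorm(tp$sigma_b, priors$sd_sigma_b)) +
    sum(stats::dnorm(tp$b[, 1L], 0, tp$sigma_b[1L], log = TRUE)) +
    sum(stats::dnorm(tp$b[, 2L], 0, tp$sigma_b[2L], log = TRUE))
  # rho ~ U(0,1) and phi ~ Dirichlet(1,1) contribute log density 0
  lp
}
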