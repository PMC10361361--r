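# Two-state hidden Markov movement model.
#
# State 1 = short-distance local movement (SDLM), state 2 = long-distance
# movement (LDM). Step lengths are gamma, turning angles wrapped Cauchy, and
# the switch probabilities gamma_12(t), gamma_21(t) follow a logit-linear
# seasonal spline in day of the biological year. State 2 is identified by
# construction: its step mean is mu1 + delta with delta > 0.

#' Emission parameters
#'
#' @param mu1_step State-1 mean step length (km), > 0.
#' @param delta Positive offset; state-2 mean step is `mu1_step + delta`.
#' @param sd_step Length-2 positive step-length SDs (km).
#' @param mu_turn Length-2 mean turning angles, radians in `(-pi, pi]`.
#' @param rho_turn Length-2 wrapped-Cauchy concentrations in `[0, 1)`.
#' @return Object of class `emission_params`.
#' @export
emission_params <- function(mu1_step, delta, sd_step, mu_turn, rho_turn) {
  stopifnot(mu1_step > 0, delta > 0, length(sd_step) == 2L, all(sd_step > 0),
            length(mu_turn) == 2L, all(mu_turn > -pi & mu_turn <= pi),
            length(rho_turn) == 2L, all(rho_turn >= 0 & rho_turn < 1))
  structure(list(mu1_step = mu1_step, delta = delta,
                 mu_step = c(mu1_step, mu1_step + delta),
                 sd_step = sd_step, mu_turn = mu_turn, rho_turn = rho_turn),
            class = "emission_params")
}

#' Transition parameters
#'
#' @param beta0 Length-2 logit-scale intercepts, order `(1->2, 2->1)`.
#' @param b K x 2 matrix of spline coefficients (columns `1->2`, `2->1`).
#' @param sigma_b Length-2 positive SDs of the spline coefficients.
#' @return Object of class `transition_params`.
#' @export
transition_params <- function(beta0, b, sigma_b) {
  b <- as.matrix(b)
  stopifnot(length(beta0) == 2L, ncol(b) == 2L,
            length(sigma_b) == 2L, all(sigma_b > 0))
  structure(list(beta0 = unname(beta0), b = unname(b),
                 sigma_b = unname(sigma_b)),
            class = "transition_params")
}

#' Initial-state probabilities per record-start day
#'
#' One categorical distribution over the two states for every distinct day of
#' the biological year on which an animal-year record begins.
#'
#' @param phi1 Named numeric vector: names are start days (1..365), values
#'   are `P(state 1)` on that day.
#' @return Object of class `initial_state_params`.
#' @export
initial_state_params <- function(phi1) {
  stopifnot(length(phi1) >= 1L, all(phi1 >= 0 & phi1 <= 1),
            !is.null(names(phi1)))
  structure(list(phi1 = phi1), class = "initial_state_params")
}

#' Full model parameter set
#'
#' @param emissions An `emission_params`.
#' @param transitions A `transition_params`.
#' @param initial An `initial_state_params`.
#' @return Object of class `hmm_params`.
#' @export
hmm_params <- function(emissions, transitions, initial) {
  stopifnot(inherits(emissions, "emission_params"),
            inherits(transitions, "transition_params"),
            inherits(initial, "initial_state_params"))
  structure(list(emissions = emissions, transitions = transitions,
                 initial = initial), class = "hmm_params")
}

#' Daily switch probabilities over the whole year
#'
#' @param tp A `transition_params`.
#' @param basis A `spline_basis` over days 1..365.
#' @return List with numeric vectors `g12` and `g21` of length 365.
#' @export
transition_probs <- function(tp, basis) {
  list(g12 = stats::plogis(tp$beta0[1L] + drop(basis$Z %*% tp$b[, 1L])),
       g21 = stats::plogis(tp$beta0[2L] + drop(basis$Z %*% tp$b[, 2L])))
}

#' Day-specific 2 x 2 transition probability matrix
#'
#' Row = state on day t-1, column = state on day t.
#'
#' @param day Integer day of the biological year (1..365).
#' @param tp A `transition_params`.
#' @param basis A `spline_basis`.
#' @return 2 x 2 stochastic matrix; rows sum to 1 exactly.
#' @export
transition_matrix <- function(day, tp, basis) {
  if (length(day) != 1L || day < 1L || day > 365L) stop("day must lie in 1..365")
  g12 <- stats::plogis(tp$beta0[1L] + seasonal_effect(day, tp$b[, 1L], basis))
  g21 <- stats::plogis(tp$beta0[2L] + seasonal_effect(day, tp$b[, 2L], basis))
  matrix(c(1 - g12, g21, g12, 1 - g21), 2L, 2L)
}

#' State-conditional emission log density of one day's observations
#'
#' Missing components contribute 0 (they are marginalized out); a day with
#' both step and turn missing therefore has log density 0 in either state.
#'
#' @param step Step length (km) or `NA`.
#' @param turn Turning angle (radians) or `NA`.
#' @param state 1 or 2.
#' @param ep An `emission_params`.
#' @return Scalar log density.
#' @export
emission_logdensity <- function(step, turn, state, ep) {
  stopifnot(state %in% c(1L, 2L))
  if (!is.na(step) && step <= 0) stop("observed step lengths must be positive")
  ld <- 0
  if (!is.na(step)) {
    sr <- gamma_shape_rate(ep$mu_step[state], ep$sd_step[state])
    ld <- ld + stats::dgamma(step, shape = sr$shape, rate = sr$rate, log = TRUE)
  }
  if (!is.na(turn))
    ld <- ld + wrapped_cauchy_logpdf(turn, ep$mu_turn[state], ep$rho_turn[state])
  ld
}

# Concatenate a list of daily_step_series into flat vectors for the C++ core.
.stack_series <- function(series) {
  if (inherits(series, "daily_step_series")) series <- list(series)
  lens <- vapply(series, nrow, integer(1))
  list(step = unlist(lapply(series, `[[`, "step_km"), use.names = FALSE),
       turn = unlist(lapply(series, `[[`, "turn_rad"), use.names = FALSE),
       start = cumsum(c(0L, lens[-length(lens)])),
       len = lens,
       start_day = vapply(series, function(s) attr(s, "start_day"), integer(1)),
       id = vapply(series, function(s) as.character(attr(s, "animal_year_id")),
                   character(1)))
}

.phi1_for <- function(initial, start_day) {
  phi1 <- initial$phi1[as.character(start_day)]
  if (anyNA(phi1))
    stop("no initial-state probability for record-start day(s) ",
         paste(unique(start_day[is.na(phi1)]), collapse = ", "))
  unname(phi1)
}

.emission_logdens <- function(stk, ep) {
  sr <- gamma_shape_rate(ep$mu_step, ep$sd_step)
  emission_logdens_cpp(stk$step, stk$turn, sr$shape, sr$rate,
                       ep$mu_turn, ep$rho_turn)
}

#' Forward-algorithm log likelihood
#'
#' Marginalizes the latent state sequence by the scaled forward recursion.
#' Missing steps/turns contribute emission log density 0 while the day's
#' transition step still applies; the transition matrix used on the move into
#' day t is the one evaluated at day t.
#'
#' @param series A `daily_step_series` or a list of them (animal-years are
#'   independent; their log likelihoods add).
#' @param params An `hmm_params` whose initial-state map covers every
#'   record-start day in `series`.
#' @param basis A `spline_basis` over days 1..365.
#' @param per_series Return the per-series vector instead of the sum.
#' @return Total log likelihood (scalar), or per-series vector.
#' @export
forward_loglik <- function(series, params, basis, per_series = FALSE) {
  stk <- .stack_series(series)
  if (length(stk$len) == 0L || any(stk$len == 0L)) stop("empty series")
  ld <- .emission_logdens(stk, params$emissions)
  tg <- transition_probs(params$transitions, basis)
  ll <- forward_cpp(ld, stk$start, stk$len, stk$start_day,
                    .phi1_for(params$initial, stk$start_day), tg$g12, tg$g21)
  if (per_series) stats::setNames(ll, stk$id) else sum(ll)
}

#' Viterbi decoding of the most probable state path
#'
#' @inheritParams forward_loglik
#' @return Integer vector of states (1 = SDLM, 2 = LDM), one per grid day;
#'   for a list input, a list of such vectors. Ties break toward state 1.
#' @export
viterbi_decode <- function(series, params, basis) {
  single <- inherits(series, "daily_step_series")
  if (single) series <- list(series)
  tg <- transition_probs(params$transitions, basis)
  out <- lapply(series, function(s) {
    stk <- .stack_series(list(s))
    ld <- .emission_logdens(stk, params$emissions)
    as.integer(viterbi_cpp(ld, stk$start_day[1L],
                           .phi1_for(params$initial, stk$start_day[1L]),
                           tg$g12, tg$g21))
  })
  if (single) out[[1L]] else out
}

#' Serialize model parameters to a flat YAML file
#'
#' @param params An `hmm_params`.
#' @param path Output path.
#' @export
write_hmm_params <- function(params, path) {
  flat <- list(
    mu1_step = params$emissions$mu1_step,
    delta = params$emissions$delta,
    sd_step = params$emissions$sd_step,
    mu_turn = params$emissions$mu_turn,
    rho_turn = params$emissions$rho_turn,
    beta0 = params$transitions$beta0,
    b_12 = params$transitions$b[, 1L],
    b_21 = params$transitions$b[, 2L],
    sigma_b = params$transitions$sigma_b,
    phi_start_day = as.integer(names(params$initial$phi1)),
    phi1 = unname(params$initial$phi1))
  yaml::write_yaml(flat, path, precision = 17L)
  invisible(path)
}

#' @rdname write_hmm_params
#' @return `read_hmm_params()` returns the reconstructed `hmm_params`.
#' @export
read_hmm_params <- function(path) {
  flat <- yaml::read_yaml(path)
  hmm_params(
    emission_params(flat$mu1_step, flat$delta, flat$sd_step,
                    flat$mu_turn, flat$rho_turn),
    transition_params(flat$beta0, cbind(flat$b_12, flat$b_21), flat$sigma_b),
    initial_state_params(stats::setNames(flat$phi1, flat$phi_start_day)))
}
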