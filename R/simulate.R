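# Synthetic collared-animal data with the exact statistical structure the
# model assumes: two latent movement states switching through seasonal
# logit-scale transition curves, gamma step lengths and wrapped-Cauchy
# turning angles per state, run-length missingness, and raw 2-h fix tables
# that reproduce the daily series after preprocessing.
#
# Preset seasonal shapes: "deer_like" has a bimodal SDLM->LDM curve (autumn
# and spring pulses separated by a winter trough) with high winter LDM->SDLM
# return probabilities; "pronghorn_like" has a single early-winter SDLM->LDM
# peak, a uniformly low return probability, smaller LDM steps and diffuse
# LDM turning angles. Emission parameters sit near the field estimates for
# the two species. Target curves are hand-specified at anchor days, then
# least-squares projected onto the K = 5 spline basis; the projected curve
# (not the hand-drawn one) is the recorded truth, so parameter recovery is
# well-defined.

.project_logit_curve <- function(anchors, basis, clamp = c(5e-4, 0.97)) {
  p <- stats::spline(anchors$day, anchors$p, xout = 1:365,
                     method = "natural")$y
  y <- stats::qlogis(pmin(pmax(p, clamp[1L]), clamp[2L]))
  X <- cbind(1, basis$Z)
  cf <- stats::lm.fit(X, y)$coefficients
  list(beta0 = unname(cf[1L]), b = unname(cf[-1L]),
       curve = stats::plogis(drop(X %*% cf)))
}

#' Preset simulation scenarios
#'
#' @param name `"deer_like"` or `"pronghorn_like"`.
#' @param n_animal_years Number of animal-year series (default 100).
#' @param start_days Pool record starts are drawn from (default 1..30:
#'   collars deployed near the July 1 year start).
#' @param basis A `spline_basis` (default: K = 5 radial basis, days 1..365).
#' @return Object of class `scenario`: `name`, `params` (true `hmm_params`),
#'   `basis`, `n_animal_years`, `start_days`, `missing_rate`,
#'   `fixes_per_day`, and the projected true transition curves
#'   `true_curves$g12/g21`.
#' @export
preset_scenario <- function(name = c("deer_like", "pronghorn_like"),
                            n_animal_years = 100L, start_days = 1:30,
                            basis = build_basis(make_knots(5, 1, 365))) {
  name <- match.arg(name)
  if (name == "deer_like") {
    em <- emission_params(mu1_step = 0.66, delta = 7.12 - 0.66,
                          sd_step = c(0.57, 6.49),
                          mu_turn = c(pi, 0), rho_turn = c(0.26, 0.70))
    a12 <- list(day = c(1, 55, 85, 114, 145, 185, 215, 250, 306, 340, 365),
                p = c(0.004, 0.003, 0.015, 0.050, 0.025, 0.010,
                      0.010, 0.030, 0.090, 0.015, 0.006))
    a21 <- list(day = c(1, 20, 70, 114, 160, 205, 250, 306, 345, 365),
                p = c(0.55, 0.59, 0.30, 0.04, 0.25, 0.40,
                      0.30, 0.12, 0.50, 0.60))
    missing_rate <- 0.08
  } else {
    em <- emission_params(mu1_step = 1.17, delta = 3.64 - 1.17,
                          sd_step = c(0.947, 3.04),
                          mu_turn = c(pi, 0), rho_turn = c(0.24, 0.12))
    a12 <- list(day = c(1, 60, 100, 151, 200, 250, 300, 365),
                p = c(0.003, 0.004, 0.030, 0.130, 0.080, 0.030,
                      0.010, 0.003))
    a21 <- list(day = c(2, 60, 120, 180, 261, 320, 365),
                p = c(0.06, 0.09, 0.12, 0.14, 0.18, 0.12, 0.08))
    missing_rate <- 0.005
  }
  f12 <- .project_logit_curve(a12, basis)
  f21 <- .project_logit_curve(a21, basis)
  tp <- transition_params(beta0 = c(f12$beta0, f21$beta0),
                          b = cbind(f12$b, f21$b),
                          sigma_b = c(max(sqrt(mean(f12$b^2)), 1e-3),
                                      max(sqrt(mean(f21$b^2)), 1e-3)))
  # animals overwhelmingly start the biological year in local movement
  phi <- initial_state_params(
    stats::setNames(rep(0.9, length(start_days)), start_days))
  structure(list(name = name,
                 params = hmm_params(em, tp, phi),
                 basis = basis,
                 n_animal_years = as.integer(n_animal_years),
                 start_days = as.integer(start_days),
                 missing_rate = missing_rate,
                 fixes_per_day = 12L,
                 true_curves = list(g12 = f12$curve, g21 = f21$curve)),
            class = "scenario")
}

#' Simulate one animal-year of states and daily observations
#'
#' The initial state is drawn from the scenario's initial-state probability
#' for `start_day`; states then evolve through the day-specific transition
#' matrices, and each day's step and turn are drawn from the state's gamma /
#' wrapped-Cauchy emission distributions. As in preprocessing, the first
#' grid day carries no step (no previous location) and the first two carry
#' no turn; steps are floored at 1 m. Uses R's RNG stream.
#'
#' @param scenario A `scenario`.
#' @param start_day First day of the record (1..365).
#' @param T Series length in days (default: through day 365); must satisfy
#'   `start_day + T - 1 <= 365`.
#' @param animal_year_id Identifier for the returned series.
#' @return List with `states` (integer vector, length `T`) and `series`
#'   (a `daily_step_series`).
#' @export
simulate_animal_year <- function(scenario, start_day,
                                 T = 365L - start_day + 1L,
                                 animal_year_id = "sim1") {
  T <- as.integer(T)
  if (T < 3L || start_day < 1L || start_day + T - 1L > 365L)
    stop("need 3 <= T and start_day + T - 1 <= 365")
  p <- scenario$params
  tg <- transition_probs(p$transitions, scenario$basis)
  phi1 <- .phi1_for(p$initial, start_day)

  states <- integer(T)
  states[1L] <- 1L + (stats::runif(1) >= phi1)
  u <- stats::runif(T - 1L)
  for (t in 2:T) {
    day <- start_day + t - 1L
    pr_switch <- if (states[t - 1L] == 1L) tg$g12[day] else tg$g21[day]
    states[t] <- if (u[t - 2L + 1L] < pr_switch) 3L - states[t - 1L]
                 else states[t - 1L]
  }

  em <- p$emissions
  sr <- gamma_shape_rate(em$mu_step, em$sd_step)
  step <- rep(NA_real_, T)
  turn <- rep(NA_real_, T)
  if (T >= 2L) {
    idx <- 2:T
    step[idx] <- pmax(stats::rgamma(length(idx), shape = sr$shape[states[idx]],
                                    rate = sr$rate[states[idx]]), 0.001)
  }
  if (T >= 3L) {
    idx <- 3:T
    turn[idx] <- rwrapped_cauchy(length(idx), em$mu_turn[states[idx]],
                                 em$rho_turn[states[idx]])
  }
  list(states = states,
       series = daily_step_series(start_day:(start_day + T - 1L), step, turn,
                                  animal_year_id = animal_year_id,
                                  bio_year = 2000L))
}

#' Drop days in run-length gaps and propagate missingness
#'
#' Gap starts occur at rate `rate / (mean_gap + 1)` per day and last
#' `1 + Geometric` days (mean `mean_gap`), so the expected fraction of
#' missing steps is about `rate` (a run of L dropped days kills L + 1
#' steps). Steps and turns adjacent to a gap are set missing exactly as the
#' preprocessing rules would.
#'
#' @param series A `daily_step_series` (complete, from
#'   [simulate_animal_year()]).
#' @param rate Target missing-step fraction in `[0, 1)`.
#' @param mean_gap Mean gap run length in days (default 2).
#' @return The series with `NA` steps/turns; dropped grid days are recorded
#'   in attribute `dropped_days` (day indices).
#' @export
inject_missingness <- function(series, rate, mean_gap = 2) {
  stopifnot(rate >= 0, rate < 1)
  n <- nrow(series)
  dropped <- integer(0)
  if (rate > 0) {
    p_start <- rate / (mean_gap + 1)
    i <- 2L
    while (i <= n) {
      if (stats::runif(1) < p_start) {
        len <- 1L + stats::rgeom(1L, 1 / mean_gap)
        dropped <- c(dropped, i:min(i + len - 1L, n))
        i <- i + len
      } else i <- i + 1L
    }
  }
  if (length(dropped)) {
    pos_na_step <- intersect(c(dropped, dropped + 1L), seq_len(n))
    pos_na_turn <- intersect(c(dropped, dropped + 1L, dropped + 2L),
                             seq_len(n))
    series$step_km[pos_na_step] <- NA_real_
    series$turn_rad[pos_na_turn] <- NA_real_
  }
  attr(series, "dropped_days") <- series$day[dropped]
  series
}

#' Simulate a full scenario (many animal-years)
#'
#' Start days are drawn uniformly from the scenario's pool and every series
#' runs through day 365; missingness is injected at the scenario rate.
#'
#' @param scenario A `scenario`.
#' @param n Number of animal-years (default `scenario$n_animal_years`).
#' @return List with `series` (list of gapped `daily_step_series`), `states`
#'   (list of true state vectors), `complete` (ungapped series) and
#'   `start_days`.
#' @export
simulate_scenario <- function(scenario, n = scenario$n_animal_years) {
  start_days <- sample(scenario$start_days, n, replace = TRUE)
  sims <- lapply(seq_len(n), function(j)
    simulate_animal_year(scenario, start_days[j],
                         animal_year_id = sprintf("%s_%03d", scenario$name, j)))
  complete <- lapply(sims, `[[`, "series")
  gapped <- lapply(complete, inject_missingness, rate = scenario$missing_rate)
  list(series = gapped, states = lapply(sims, `[[`, "states"),
       complete = complete, start_days = start_days)
}

# biological day -> calendar date in bio year starting July 1 of `year`
# (Feb 29, when present, is skipped so the grid inverse is exact)
.bio_day_to_date <- function(day, year) {
  dates <- seq(as.Date(sprintf("%d-07-01", year)),
               as.Date(sprintf("%d-06-30", year + 1L)), by = "day")
  dates <- dates[format(dates, "%m-%d") != "02-29"]
  dates[day]
}

#' Emit a raw 2-h GPS fix table consistent with a daily series
#'
#' Daily 06:00 positions are dead-reckoned from the step/turn sequence
#' (start at the origin, initial bearing 0); sub-daily fixes at the 2-h
#' schedule are linear interpolations between daily positions with small
#' Gaussian jitter, the 06:00 fix kept exact so preprocessing recovers the
#' daily series. Dropped days emit no fixes.
#'
#' @param series A complete `daily_step_series` (no missing steps except the
#'   structural leading ones), e.g. `simulate_scenario()$complete[[j]]`.
#' @param dropped_days Day indices to leave without fixes (e.g. the
#'   `dropped_days` attribute of the gapped series).
#' @param animal_id,bio_year Identifiers for the output table.
#' @param jitter_m SD (meters) of the sub-daily interpolation jitter.
#' @param fixes_per_day Fix schedule density (12 = every 2 h).
#' @return data.frame with columns `animal_id`, `timestamp`, `x`, `y`
#'   (planar meters), attribute `coords = "projected"`.
#' @export
emit_raw_fixes <- function(series, dropped_days = integer(0),
                           animal_id = "a1", bio_year = 2000L,
                           jitter_m = 20, fixes_per_day = 12L) {
  n <- nrow(series)
  if (anyNA(series$step_km[-1L]))
    stop("emit_raw_fixes needs a complete series; pass dropped days separately")
  # dead-reckoned daily positions (meters)
  bearing <- numeric(n)
  x <- numeric(n); y <- numeric(n)
  for (t in 2:n) {
    bearing[t] <- if (t >= 3L) wrap_angle(bearing[t - 1L] + series$turn_rad[t])
                  else 0
    x[t] <- x[t - 1L] + series$step_km[t] * 1000 * cos(bearing[t])
    y[t] <- y[t - 1L] + series$step_km[t] * 1000 * sin(bearing[t])
  }
  hours <- seq(0, 24 - 24 / fixes_per_day, by = 24 / fixes_per_day)
  keep <- setdiff(seq_len(n), match(dropped_days, series$day))
  rows <- lapply(keep, function(t) {
    date <- .bio_day_to_date(series$day[t], bio_year)
    frac <- (hours - 6) / 24            # position along the 06:00->06:00 leg
    xi <- x[t] + ifelse(frac >= 0 & t < n, frac * (x[min(t + 1L, n)] - x[t]),
                        ifelse(frac < 0 & t > 1L, frac * (x[t] - x[t - 1L]), 0))
    yi <- y[t] + ifelse(frac >= 0 & t < n, frac * (y[min(t + 1L, n)] - y[t]),
                        ifelse(frac < 0 & t > 1L, frac * (y[t] - y[t - 1L]), 0))
    jx <- stats::rnorm(length(hours), 0, jitter_m)
    jy <- stats::rnorm(length(hours), 0, jitter_m)
    exact <- hours == 6
    data.frame(animal_id = animal_id,
               timestamp = as.POSIXct(paste0(date, " 00:00:00"), tz = "UTC") +
                 hours * 3600,
               x = xi + ifelse(exact, 0, jx),
               y = yi + ifelse(exact, 0, jy))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "coords") <- "projected"
  out
}

#' Write a fix table as CSV (ISO-8601 timestamps)
#' @param fixes data.frame from [emit_raw_fixes()].
#' @param path Output path.
#' @export
write_fixes <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
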