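# Post hoc seasonal summaries: daily marginal probability of the
# long-distance movement (LDM) state, and derivative-based seasonal event
# timing (fall start = first maximum of the derivative, fall end = first
# minimum, spring start = second maximum, spring end = second minimum).

#' Daily marginal probability of the LDM state for one parameter draw
#'
#' Chapman-Kolmogorov propagation: the state distribution is anchored on day
#' 1 of the biological year (the day-1 initial-state probabilities when a
#' record starts on day 1, else a uniform (0.5, 0.5) start) and pushed
#' through the day-specific transition matrices, `p_t = p_{t-1} Gamma(t)`.
#'
#' @param params An `hmm_params`.
#' @param basis A `spline_basis`.
#' @return Numeric vector of length 365: `P(LDM on day t)`.
#' @export
marginal_ldm_curve <- function(params, basis) {
  tg <- transition_probs(params$transitions, basis)
  phi1 <- params$initial$phi1["1"]
  p1 <- if (is.na(phi1)) 0.5 else unname(phi1)
  out <- numeric(365)
  p <- c(p1, 1 - p1)
  out[1L] <- p[2L]
  for (t in 2:365) {
    p <- c(p[1L] * (1 - tg$g12[t]) + p[2L] * tg$g21[t],
           p[1L] * tg$g12[t] + p[2L] * (1 - tg$g21[t]))
    out[t] <- p[2L]
  }
  out
}

# per-draw curves as 365 x n_draws matrices
.curve_draws <- function(samples) {
  d <- samples$draws
  Z <- samples$basis$Z
  K <- ncol(Z)
  G12 <- stats::plogis(sweep(Z %*% t(d[, paste0("b12_", seq_len(K))]),
                             2, d[, "beta0_12"], "+"))
  G21 <- stats::plogis(sweep(Z %*% t(d[, paste0("b21_", seq_len(K))]),
                             2, d[, "beta0_21"], "+"))
  p1 <- if ("phi1_d1" %in% colnames(d)) d[, "phi1_d1"] else
    rep(0.5, nrow(d))
  P <- matrix(NA_real_, 365, nrow(d))
  a <- p1; b <- 1 - p1
  P[1L, ] <- b
  for (t in 2:365) {
    a_new <- a * (1 - G12[t, ]) + b * G21[t, ]
    b <- a * G12[t, ] + b * (1 - G21[t, ])
    a <- a_new
    P[t, ] <- b
  }
  list(g12 = G12, g21 = G21, pldm = P)
}

#' Posterior seasonal curves (daily medians and HPDIs)
#'
#' @param samples A `posterior_samples`.
#' @param mass HPDI mass, default 0.90.
#' @return data.frame with one row per day 1..365 and columns
#'   `g12_median/lo/hi`, `g21_median/lo/hi`, `pldm_median/lo/hi`.
#' @export
seasonal_curves <- function(samples, mass = 0.90) {
  cd <- .curve_draws(samples)
  summ <- function(M, nm) {
    ints <- apply(M, 1, hpdi, mass = mass)
    out <- data.frame(apply(M, 1, stats::median), ints[1L, ], ints[2L, ])
    names(out) <- paste0(nm, c("_median", "_lo", "_hi"))
    out
  }
  cbind(data.frame(day = 1:365),
        summ(cd$g12, "g12"), summ(cd$g21, "g21"), summ(cd$pldm, "pldm"))
}

#' First derivative of a daily curve
#'
#' Optional centered moving-average smoothing (edge windows shrink), then
#' central finite differences on interior days and one-sided differences at
#' the ends.
#'
#' @param curve Numeric vector of per-day values (>= 3 days).
#' @param smooth_window Odd moving-average width in days; 1 disables
#'   smoothing. Default 7.
#' @return Numeric derivative, same length as `curve` (units: per day).
#' @export
curve_derivative <- function(curve, smooth_window = 7L) {
  n <- length(curve)
  if (n < 3L) stop("need at least 3 days")
  h <- smooth_window %/% 2L
  sm <- if (h > 0L) {
    vapply(seq_len(n),
           function(i) mean(curve[max(1L, i - h):min(n, i + h)]), numeric(1))
  } else curve
  d <- numeric(n)
  d[1L] <- sm[2L] - sm[1L]
  d[n] <- sm[n] - sm[n - 1L]
  if (n > 2L) d[2:(n - 1L)] <- (sm[3:n] - sm[1:(n - 2L)]) / 2
  d
}

# indices of local maxima of x with topographic prominence >= floor
.peaks <- function(x, prominence) {
  n <- length(x)
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  keep <- vapply(cand, function(i) {
    h <- x[i]
    left <- if (i > 1L) {
      higher <- which(x[1:(i - 1L)] > h)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(x[lo:(i - 1L)])
    } else h
    right <- if (i < n) {
      higher <- which(x[(i + 1L):n] > h)
      hi <- if (length(higher)) i + min(higher) - 1L else n
      min(x[(i + 1L):hi])
    } else h
    (h - max(left, right)) >= prominence
  }, logical(1))
  cand[keep]
}

#' Seasonal event days from a derivative curve
#'
#' Scans day 1 onward: fall start = first local maximum of the derivative,
#' fall end = first subsequent local minimum, spring start = the next local
#' maximum, spring end = the next local minimum. Extrema must clear a
#' topographic-prominence floor; events whose required predecessor is absent
#' come back `NA`.
#'
#' @param derivative Per-day derivative over the full year.
#' @param prominence Prominence floor (per day), default 0.005.
#' @param guard_days Extrema on days `<= guard_days` are ignored (default
#'   10). The marginal-LDM propagation relaxes from its day-1 anchor toward
#'   the seasonal level over a few days, and that transient would otherwise
#'   masquerade as the year's first event.
#' @return Named numeric vector
#'   `c(fall_start, fall_end, spring_start, spring_end)` (day indices, `NA`
#'   when undefined).
#' @export
event_days <- function(derivative, prominence = 0.005, guard_days = 10L) {
  maxima <- .peaks(derivative, prominence)
  minima <- .peaks(-derivative, prominence)
  maxima <- maxima[maxima > guard_days]
  minima <- minima[minima > guard_days]
  out <- c(fall_start = NA_real_, fall_end = NA_real_,
           spring_start = NA_real_, spring_end = NA_real_)
  nxt <- function(cands, after) {
    ok <- cands[cands > after]
    if (length(ok)) ok[1L] else NA_real_
  }
  out["fall_start"] <- if (length(maxima)) maxima[1L] else NA_real_
  if (!is.na(out["fall_start"])) {
    out["fall_end"] <- nxt(minima, out["fall_start"])
    if (!is.na(out["fall_end"])) {
      out["spring_start"] <- nxt(maxima, out["fall_end"])
      if (!is.na(out["spring_start"]))
        out["spring_end"] <- nxt(minima, out["spring_start"])
    }
  }
  out
}

#' Per-draw event timing and its posterior summary
#'
#' Computes the marginal LDM curve, its (smoothed) derivative and the four
#' seasonal event days for every posterior draw, then summarizes each event
#' over the draws where it is defined.
#'
#' @param samples A `posterior_samples`.
#' @param smooth_window,prominence,guard_days Passed to
#'   [curve_derivative()] / [event_days()].
#' @param mass HPDI mass, default 0.90.
#' @return data.frame with columns `event`, `median`, `lo`, `hi`,
#'   `frac_undefined`; events undefined in every draw get `NA` summaries.
#' @export
event_timing <- function(samples, smooth_window = 7L, prominence = 0.005,
                         guard_days = 10L, mass = 0.90) {
  cd <- .curve_draws(samples)
  ev <- t(apply(cd$pldm, 2, function(p)
    event_days(curve_derivative(p, smooth_window), prominence, guard_days)))
  summarize_events(ev, mass = mass)
}

#' Summarize per-draw event days
#'
#' @param events Matrix: one row per draw, columns `fall_start`, `fall_end`,
#'   `spring_start`, `spring_end` (NA where undefined in that draw).
#' @param mass HPDI mass, default 0.90.
#' @return data.frame with `event`, `median`, `lo`, `hi`, `frac_undefined`.
#' @export
summarize_events <- function(events, mass = 0.90) {
  events <- as.matrix(events)
  out <- lapply(colnames(events), function(nm) {
    x <- events[, nm]
    def <- x[!is.na(x)]
    if (length(def) == 0L)
      return(data.frame(event = nm, median = NA_real_, lo = NA_real_,
                        hi = NA_real_, frac_undefined = 1))
    int <- if (length(def) >= 20L) hpdi(def, mass) else range(def)
    data.frame(event = nm, median = stats::median(def),
               lo = int[1L], hi = int[2L],
               frac_undefined = 1 - length(def) / length(x))
  })
  do.call(rbind, out)
}
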