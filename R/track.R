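# GPS fix tables -> per-animal-year daily step/turn series.
#
# Conventions fixed here and relied on everywhere downstream:
#   * biological year runs July 1 (day 1) to June 30 (day 365); Feb 29 shares
#     Feb 28's index so every year has 365 days
#   * one location per day, the fix closest in time to 06:00 (earlier fix wins
#     exact ties); 06:00 is read in the timestamps' own clock
#   * step on day t = distance (km) from day t-1 to day t, defined only when
#     both days are observed; turn on day t needs days t-2, t-1, t
#   * turning angles are counterclockwise-positive radians in (-pi, pi]

# cumulative day offsets of each calendar month within the July-June year
# (non-leap month lengths; Feb 29 collapses onto Feb 28)
.BIO_MONTH_START <- {
  len <- c(31, 31, 30, 31, 30, 31, 31, 28, 31, 30, 31, 30) # Jul..Jun
  stats::setNames(cumsum(c(0L, len[-12])),
                  c(7L, 8L, 9L, 10L, 11L, 12L, 1L, 2L, 3L, 4L, 5L, 6L))
}

#' Map a timestamp to its biological year and day index
#'
#' The biological year runs July 1 through June 30 and is labelled by the
#' calendar year containing its July 1 start. Day indices run 1..365; in leap
#' years Feb 29 shares Feb 28's index so the grid length never changes.
#'
#' @param timestamp `POSIXct`/`POSIXlt` or `Date` vector.
#' @return A data.frame with integer columns `bio_year` and `day`.
#' @examples
#' assign_biological_day(as.Date(c("2019-07-01", "2020-06-30", "2020-02-29")))
#' @export
assign_biological_day <- function(timestamp) {
  lt <- as.POSIXlt(timestamp)
  mon <- lt$mon + 1L   # 1..12
  mday <- lt$mday
  year <- lt$year + 1900L
  bio_year <- ifelse(mon >= 7L, year, year - 1L)
  day <- .BIO_MONTH_START[as.character(mon)] +
    pmin(mday, ifelse(mon == 2L, 28L, 31L))
  data.frame(bio_year = as.integer(bio_year), day = as.integer(unname(day)))
}

#' Read a GPS fix table from delimited text
#'
#' Expects columns `animal_id`, `timestamp` (ISO-8601, a single consistent
#' local clock), `x`, `y`. Coordinates are either planar meters (projected
#' CRS) or lon/lat degrees; the choice only matters when steps and bearings
#' are computed.
#'
#' @param path CSV file path.
#' @param coords `"projected"` (meters) or `"geographic"` (lon/lat degrees).
#' @return A data.frame of fixes sorted by animal and time, with duplicate
#'   timestamps within an animal dropped, carrying attribute `coords`.
#' @export
read_fixes <- function(path, coords = c("projected", "geographic")) {
  coords <- match.arg(coords)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "x", "y")
  if (!all(need %in% names(raw)))
    stop("fix table must have columns: ", paste(need, collapse = ", "))
  raw$timestamp <- as.POSIXct(raw$timestamp, tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                             "%Y-%m-%d %H:%M:%OS",
                                             "%Y-%m-%d"))
  if (anyNA(raw$timestamp)) stop("unparseable timestamps in ", path)
  if (!all(is.finite(raw$x)) || !all(is.finite(raw$y)))
    stop("non-finite coordinates in ", path)
  raw <- raw[order(raw$animal_id, raw$timestamp), , drop = FALSE]
  dup <- duplicated(raw[, c("animal_id", "timestamp")])
  raw <- raw[!dup, , drop = FALSE]
  rownames(raw) <- NULL
  attr(raw, "coords") <- coords
  raw
}

#' Keep one fix per calendar day (the fix nearest 06:00)
#'
#' @param fixes data.frame of one animal's fixes sorted by time, with a
#'   `timestamp` column. 06:00 is interpreted in the timestamps' own clock;
#'   exact ties (e.g. 05:00 vs 07:00) keep the earlier fix.
#' @return The subset of rows retained, one per calendar day.
#' @export
resample_daily <- function(fixes) {
  if (nrow(fixes) == 0L) return(fixes)
  lt <- as.POSIXlt(fixes$timestamp)
  date_key <- format(fixes$timestamp, "%Y-%m-%d")
  secs <- lt$hour * 3600 + lt$min * 60 + lt$sec
  off <- abs(secs - 6 * 3600)
  # stable order(): among equal offsets the earlier (first) fix is kept
  keep <- vapply(split(seq_len(nrow(fixes)), date_key),
                 function(i) i[which.min(off[i])], integer(1))
  out <- fixes[sort(unname(keep)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coords") <- attr(fixes, "coords")
  out
}

wrap_angle <- function(x) {
  r <- x %% (2 * pi)
  ifelse(r > pi, r - 2 * pi, r)
}

# planar or great-circle step (km) and bearing (radians, CCW from +x / east)
.steps_bearings <- function(x, y, geographic) {
  n <- length(x)
  if (geographic) {
    p <- cbind(x, y)
    d <- geosphere::distGeo(p[-n, , drop = FALSE], p[-1L, , drop = FALSE]) / 1000
    # geosphere bearing: degrees clockwise from north -> radians CCW from east
    brg <- wrap_angle(pi / 2 - geosphere::bearing(p[-n, , drop = FALSE],
                                                 p[-1L, , drop = FALSE]) * pi / 180)
  } else {
    dx <- diff(x); dy <- diff(y)
    d <- sqrt(dx^2 + dy^2) / 1000
    brg <- atan2(dy, dx)
  }
  list(step = d, bearing = brg)
}

#' Build one animal-year's daily step/turn series
#'
#' @param daily_fixes data.frame with at most one fix per day (see
#'   [resample_daily()]), columns `timestamp`, `x`, `y`, all belonging to one
#'   animal and one biological year.
#' @param bio_year Integer biological-year label the fixes must fall in.
#' @param animal_year_id Identifier stored on the result.
#' @param coords `"projected"` or `"geographic"` (defaults to the fixes'
#'   `coords` attribute, else projected).
#' @param min_step_km Floor for step lengths, default 0.001 km: a recorded
#'   zero-length day would have zero gamma density, and sub-meter daily
#'   displacement is below collar precision anyway.
#' @return A `daily_step_series`: data.frame with columns `day`, `step_km`,
#'   `turn_rad` on the complete grid `start_day..last observed day` (missing
#'   days carry `NA`), with attributes `animal_year_id`, `bio_year`,
#'   `start_day`.
#' @export
build_step_series <- function(daily_fixes, bio_year, animal_year_id = "ay1",
                              coords = NULL, min_step_km = 0.001) {
  if (is.null(coords))
    coords <- attr(daily_fixes, "coords") %||% "projected"
  bd <- assign_biological_day(daily_fixes$timestamp)
  ok <- bd$bio_year == bio_year
  daily_fixes <- daily_fixes[ok, , drop = FALSE]
  days <- bd$day[ok]
  if (nrow(daily_fixes) < 3L)
    stop("animal-year ", animal_year_id, ": fewer than 3 daily fixes in bio year ",
         bio_year, "; rejected")
  # Feb 29 shares Feb 28's index, so a leap year can put two calendar days on
  # one grid day: keep the earlier (Feb 28) fix. Any other collision is a
  # caller error.
  if (anyDuplicated(days)) {
    lt <- as.POSIXlt(daily_fixes$timestamp)
    dup <- duplicated(days)
    if (!all(lt$mon[dup] == 1L & lt$mday[dup] == 29L))
      stop("more than one fix per day; run resample_daily() first")
    daily_fixes <- daily_fixes[!dup, , drop = FALSE]
    days <- days[!dup]
  }
  o <- order(days)
  days <- days[o]
  x <- daily_fixes$x[o]; y <- daily_fixes$y[o]

  sb <- .steps_bearings(x, y, geographic = identical(coords, "geographic"))
  step_obs <- pmax(sb$step, min_step_km)

  start_day <- days[1L]
  grid <- start_day:days[length(days)]
  step <- rep(NA_real_, length(grid))
  turn <- rep(NA_real_, length(grid))
  # step i spans days[i] -> days[i+1]; defined only across consecutive days
  consec <- diff(days) == 1L
  step[match(days[-1L][consec], grid)] <- step_obs[consec]
  # turn at days[i+1] needs steps into days[i] and days[i+1] both defined
  if (length(consec) >= 2L) {
    tri <- consec[-length(consec)] & consec[-1L]
    turn[match(days[-(1:2)][tri], grid)] <-
      wrap_angle(diff(sb$bearing))[tri]
  }
  daily_step_series(day = grid, step_km = step, turn_rad = turn,
                    animal_year_id = animal_year_id, bio_year = bio_year)
}

#' Construct/validate a daily step series
#'
#' @param day Integer day-of-biological-year grid, strictly increasing by 1.
#' @param step_km Step lengths (km), `NA` where unobserved; positive otherwise.
#' @param turn_rad Turning angles in `(-pi, pi]`, `NA` where unobserved.
#' @param animal_year_id,bio_year Identifiers stored as attributes.
#' @return Object of class `daily_step_series`.
#' @export
daily_step_series <- function(day, step_km, turn_rad,
                              animal_year_id = "ay1", bio_year = 0L) {
  day <- as.integer(day)
  stopifnot(length(day) >= 1L, length(step_km) == length(day),
            length(turn_rad) == length(day))
  if (length(day) > 1L && any(diff(day) != 1L))
    stop("day grid must increase by exactly 1 (missing days carry NA)")
  if (day[1L] < 1L || day[length(day)] > 365L)
    stop("day indices must lie in 1..365")
  if (any(step_km <= 0, na.rm = TRUE))
    stop("observed steps must be positive")
  if (any(turn_rad <= -pi | turn_rad > pi, na.rm = TRUE))
    stop("turning angles must lie in (-pi, pi]")
  if (!is.na(turn_rad[1L]))
    stop("the first day's turning angle is undefined and must be NA")
  out <- data.frame(day = day, step_km = as.numeric(step_km),
                    turn_rad = as.numeric(turn_rad))
  attr(out, "animal_year_id") <- animal_year_id
  attr(out, "bio_year") <- as.integer(bio_year)
  attr(out, "start_day") <- day[1L]
  class(out) <- c("daily_step_series", "data.frame")
  out
}

#' Write / read daily step series as CSV
#'
#' Missing steps and turns are written as empty fields.
#'
#' @param series A `daily_step_series` or list of them.
#' @param path Output CSV path.
#' @export
write_daily_series <- function(series, path) {
  if (inherits(series, "daily_step_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(animal_year_id = attr(s, "animal_year_id"),
               bio_year = attr(s, "bio_year"),
               day = s$day, step_km = s$step_km, turn_rad = s$turn_rad)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_daily_series
#' @return `read_daily_series()` returns a named list of `daily_step_series`.
#' @export
read_daily_series <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$animal_year_id), function(g) {
    g <- g[order(g$day), , drop = FALSE]
    daily_step_series(g$day, g$step_km, g$turn_rad,
                      animal_year_id = g$animal_year_id[1L],
                      bio_year = g$bio_year[1L])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
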