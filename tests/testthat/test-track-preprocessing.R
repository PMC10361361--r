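test_that("biological-year day mapping has July 1 = 1, June 30 = 365, Feb 29 collapsed", {
  x <- assign_biological_day(as.Date(c("2018-07-01", "2019-06-30",
                                       "2020-02-29", "2020-02-28")))
  expect_equal(x$day, c(1L, 365L, x$day[4L], x$day[4L]))
  expect_equal(x$bio_year, c(2018L, 2018L, 2019L, 2019L))

  # enumerate a leap-containing and a plain biological year: the mapping must
  # be onto 1..365, nondecreasing, with Feb 29 the only collision
  for (y in c(2018L, 2019L)) {            # 2019-20 contains Feb 29 2020
    dates <- seq(as.Date(sprintf("%d-07-01", y)),
                 as.Date(sprintf("%d-06-30", y + 1L)), by = "day")
    d <- assign_biological_day(dates)$day
    expect_equal(sort(unique(d)), 1:365)
    expect_true(all(diff(d) %in% c(0L, 1L)))
    dup <- dates[duplicated(d)]
    if (length(dup)) expect_equal(format(dup, "%m-%d"), "02-29")
  }
})

test_that("daily resampling keeps the fix nearest 06:00, earlier on ties", {
  mk <- function(times) data.frame(
    animal_id = "a", timestamp = as.POSIXct(times, tz = "UTC"),
    x = seq_along(times), y = 0)
  f <- resample_daily(mk(c("2020-07-01 04:00", "2020-07-01 06:10",
                           "2020-07-01 23:50")))
  expect_equal(nrow(f), 1L)
  expect_equal(f$x, 2)                                     # the 06:10 fix

  one_per_day <- mk(c("2020-07-01 06:00", "2020-07-02 09:00"))
  expect_equal(resample_daily(one_per_day)$x, one_per_day$x)

  tie <- resample_daily(mk(c("2020-07-01 05:00", "2020-07-01 07:00")))
  expect_equal(tie$x, 1)                                   # earlier fix wins

  empty <- data.frame(animal_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      x = numeric(0), y = numeric(0))
  expect_equal(nrow(resample_daily(empty)), 0L)
})

test_that("step/turn construction: straight path, right-angle sign, gaps, rejection", {
  mk <- function(days, x, y) data.frame(
    animal_id = "a",
    timestamp = as.POSIXct(sprintf("2020-07-%02d 06:00", days), tz = "UTC"),
    x = x, y = y)

  s <- build_step_series(mk(1:3, c(0, 0, 0), c(0, 1000, 2000)), 2020L)
  expect_equal(s$step_km, c(NA, 1, 1))
  expect_equal(s$turn_rad, c(NA, NA, 0))

  # north then east = clockwise right turn = -pi/2 under CCW-positive angles
  s <- build_step_series(mk(1:3, c(0, 0, 1000), c(0, 1000, 1000)), 2020L)
  expect_equal(s$turn_rad[3L], -pi / 2)

  # a one-day hole: grid day present, spanning step/turn missing
  s <- build_step_series(mk(c(1, 2, 4, 5), c(0, 0, 0, 0),
                            c(0, 1000, 3000, 4000)), 2020L)
  expect_equal(s$day, 1:5)
  expect_equal(is.na(s$step_km), c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_true(all(is.na(s$turn_rad)))     # no 3 consecutive observed days

  expect_error(build_step_series(mk(1:2, c(0, 0), c(0, 1000)), 2020L),
               "fewer than 3")
})

test_that("dead-reckoned positions round-trip through step/turn construction", {
  set.seed(42)
  T <- 40L
  step <- runif(T, 0.1, 5)            # km
  turn <- runif(T, -pi + 1e-6, pi)
  bearing <- numeric(T); x <- numeric(T); y <- numeric(T)
  for (t in 2:T) {
    bearing[t] <- if (t >= 3L) bearing[t - 1L] + turn[t] else 0
    x[t] <- x[t - 1L] + 1000 * step[t] * cos(bearing[t])
    y[t] <- y[t - 1L] + 1000 * step[t] * sin(bearing[t])
  }
  fx <- data.frame(animal_id = "a",
                   timestamp = as.POSIXct("2020-07-01 06:00", tz = "UTC") +
                     86400 * (0:(T - 1L)),
                   x = x, y = y)
  s <- build_step_series(fx, 2020L)
  expect_equal(s$step_km[2:T], step[2:T], tolerance = 1e-9)
  expect_equal(s$turn_rad[3:T],
               vapply(turn[3:T], function(a) {
                 r <- a %% (2 * pi); if (r > pi) r - 2 * pi else r
               }, numeric(1)),
               tolerance = 1e-9)
})

test_that("geodesic mode matches planar distances for small equatorial offsets", {
  # ~1 km steps at the equator: one degree longitude ~ 111.32 km
  lon <- c(0, 0.009, 0.018); lat <- c(0, 0, 0)
  fx <- data.frame(animal_id = "a",
                   timestamp = as.POSIXct("2020-07-01 06:00", tz = "UTC") +
                     86400 * (0:2),
                   x = lon, y = lat)
  attr(fx, "coords") <- "geographic"
  s <- build_step_series(fx, 2020L)
  expect_equal(s$step_km[2:3], rep(0.009 * 111.3195, 2), tolerance = 5e-3)
  expect_equal(s$turn_rad[3L], 0, tolerance = 1e-6)
})

test_that("series CSV writer/reader round-trips including the missing sentinel", {
  s <- daily_step_series(10:14, c(NA, 1.5, NA, 2.5, 3.5),
                         c(NA, NA, NA, 0.5, -3), "ay_x", 2019L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_daily_series(s, path)
  expect_false(any(grepl("NA", readLines(path))))  # empty-field sentinel
  back <- read_daily_series(path)[["ay_x"]]
  expect_equal(back$step_km, s$step_km)
  expect_equal(back$turn_rad, s$turn_rad)
  expect_equal(attr(back, "bio_year"), 2019L)
  expect_equal(attr(back, "start_day"), 10L)
})

test_that("series grid and value invariants are enforced", {
  expect_error(daily_step_series(c(1, 3), c(NA, 1), c(NA, NA)), "exactly 1")
  expect_error(daily_step_series(1:2, c(NA, -1), c(NA, NA)), "positive")
  expect_error(daily_step_series(1:2, c(NA, 1), c(0.1, NA)), "must be NA")
  expect_error(daily_step_series(1:2, c(NA, 1), c(NA, 4)), "-pi")
})
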