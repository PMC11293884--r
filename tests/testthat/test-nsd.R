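t0 <- function() as.POSIXct("2023-01-01 00:00:00", tz = "UTC")

test_that("daily NSD uses the fix nearest local noon, in km^2", {
  # single fix at the origin
  f <- tibble::tibble(t = t0(), x = 0, y = 0)
  expect_equal(compute_nsd(f, c(0, 0))$nsd, 0)
  # 3 km east, 4 km north: 25 km^2
  f2 <- tibble::tibble(t = t0() + 12 * 3600, x = 3000, y = 4000)
  expect_equal(compute_nsd(f2, c(0, 0))$nsd, 25)
  # two fixes the same day at 09:00 and 16:00: 09:00 wins (3 h vs 4 h)
  f3 <- tibble::tibble(
    t = t0() + c(9, 16) * 3600,
    x = c(1000, 9999), y = 0
  )
  out <- compute_nsd(f3, c(0, 0))
  expect_equal(nrow(out), 1)
  expect_equal(out$nsd, 1)
})

test_that("natal range recovers the center and radius of resident fixes", {
  set.seed(41)
  n_days <- 40
  # 6 fixes/day uniform in a 2 km disc around (10, 20) km
  nper <- 6
  r <- 2000 * sqrt(runif(n_days * nper))
  th <- runif(n_days * nper, 0, 2 * pi)
  f <- tibble::tibble(
    t = t0() + rep(0:(n_days - 1), each = nper) * 86400 +
      rep(seq(0, 20, length.out = nper) * 3600, n_days),
    x = 10000 + r * cos(th),
    y = 20000 + r * sin(th)
  )
  nat <- estimate_natal_range(f)
  expect_true(nat$ok)
  expect_lt(sqrt(sum((nat$origin - c(10000, 20000))^2)), 500)
  # 0.95 quantile of distance for uniform disc of radius R is R*sqrt(.95)
  expect_gt(nat$radius_m, 1700)
  expect_lt(nat$radius_m, 2150)
})

test_that("monotone drift is flagged as having no natal range", {
  f <- tibble::tibble(
    t = t0() + (0:239) * 6 * 3600,
    x = (0:239) * 250, # 1 km/day drift
    y = 0
  )
  nat <- estimate_natal_range(f)
  expect_false(nat$ok)
  expect_match(nat$reason, "drift")
})

test_that("a point-stationary animal gets radius zero at its location", {
  f <- tibble::tibble(t = t0() + (0:199) * 6 * 3600, x = 777, y = -44)
  nat <- estimate_natal_range(f)
  expect_true(nat$ok)
  expect_equal(nat$origin, c(777, -44))
  expect_equal(nat$radius_m, 0)
})

# build an NSD series directly (one value per day)
nsd_series <- function(nsd) {
  tibble::tibble(
    day = as.Date("2023-01-01") + seq_along(nsd) - 1,
    x = 1000 * sqrt(nsd), y = 0, nsd = nsd
  )
}

test_that("excursion with return is exploratory, covering ramp and away time", {
  set.seed(42)
  nsd <- c(
    abs(rnorm(30, 0.2, 0.1)), # natal plateau
    seq(1.5, 880, length.out = 10), # ramp out
    rnorm(30, 900, 30), # away plateau (still an excursion)
    seq(880, 1.5, length.out = 10), # ramp home
    abs(rnorm(40, 0.2, 0.1)) # back in the natal range
  )
  seg <- classify_states(nsd_series(nsd), radius_m = 1000)
  expect_equal(seg$state, c("natal", "exploratory", "natal"))
  # change points within 3 days of the constructed ones (days 31 and 80)
  expect_lte(abs(as.integer(seg$t_start[2] - as.Date("2023-01-31"))), 3)
  expect_lte(abs(as.integer(seg$t_end[2] - as.Date("2023-03-21"))), 3)
})

test_that("an excursion that never returns is a departure", {
  set.seed(43)
  nsd <- c(abs(rnorm(30, 0.2, 0.1)), seq(2, 2500, length.out = 25))
  seg <- classify_states(nsd_series(nsd), radius_m = 1000)
  expect_equal(seg$state, c("natal", "departure"))
  expect_equal(seg$t_start[2], as.Date("2023-01-31"))
})

test_that("post-departure plateaus split by the six-month rule", {
  set.seed(44)
  ramp <- seq(2, 2500, length.out = 15)
  natal <- abs(rnorm(30, 0.2, 0.1))
  # 120-day plateau (< 183): transient home range
  seg <- classify_states(
    nsd_series(c(natal, ramp, rnorm(120, 2500, 40))),
    radius_m = 1000
  )
  expect_equal(
    seg$state, c("natal", "departure", "transient_home_range")
  )
  # 200-day plateau (>= 183): established
  seg2 <- classify_states(
    nsd_series(c(natal, ramp, rnorm(200, 2500, 40))),
    radius_m = 1000
  )
  expect_equal(seg2$state, c("natal", "departure", "established"))
})

test_that("short sallies below away_min_days stay natal", {
  set.seed(45)
  nsd <- c(abs(rnorm(20, 0.2, 0.1)), rep(5, 3), abs(rnorm(20, 0.2, 0.1)))
  seg <- classify_states(nsd_series(nsd), radius_m = 1000)
  expect_equal(seg$state, "natal")
})

test_that("segments partition the classified span without gaps or overlap", {
  set.seed(46)
  nsd <- c(
    abs(rnorm(35, 0.3, 0.15)), seq(2, 600, length.out = 8),
    rnorm(25, 650, 20), seq(600, 2, length.out = 8),
    abs(rnorm(20, 0.3, 0.15)), seq(2, 3000, length.out = 20),
    rnorm(60, 3100, 60)
  )
  series <- nsd_series(nsd)
  seg <- classify_states(series, radius_m = 1000)
  days <- attr(seg, "day_states")
  expect_equal(nrow(days), nrow(series))
  expect_false(any(is.na(days$state)))
  # segment intervals tile the day sequence
  expect_equal(seg$t_start[1], series$day[1])
  expect_equal(seg$t_end[nrow(seg)], series$day[nrow(series)])
  if (nrow(seg) > 1) {
    expect_true(all(seg$t_start[-1] == seg$t_end[-nrow(seg)] + 1))
  }
})

test_that("raising the return threshold never shrinks natal coverage", {
  set.seed(47)
  for (rep in 1:10) {
    nsd <- abs(cumsum(rnorm(120, 0.5, 4))) / 3
    s1 <- classify_states(nsd_series(nsd), radius_m = 1000,
      params = segmentation_params(return_threshold = 1.0))
    s2 <- classify_states(nsd_series(nsd), radius_m = 1000,
      params = segmentation_params(return_threshold = 1.5))
    d1 <- attr(s1, "day_states")
    d2 <- attr(s2, "day_states")
    natal1 <- d1$day[d1$state == "natal"]
    natal2 <- d2$day[d2$state == "natal"]
    expect_true(all(natal1 %in% natal2))
    dep1 <- d1$day[d1$state == "departure"]
    dep2 <- d2$day[d2$state == "departure"]
    if (length(dep2)) expect_true(all(dep2 %in% dep1))
  }
})

test_that("state summaries report path and displacement correctly", {
  # 10 days of 1 km/day due east: path 10 km, displacement 10 km
  f <- tibble::tibble(
    t = t0() + (0:59) * 4 * 3600,
    x = (0:59) * 1000 / 6, y = 0
  )
  seg <- tibble::tibble(
    state = "departure",
    t_start = as.Date("2023-01-01"), t_end = as.Date("2023-01-10"),
    duration_days = 10L, displacement_km = 10
  )
  out <- summarize_states(seg, f, c(0, 0))
  expect_equal(out$path_km, 59 / 6, tolerance = 1e-9)
  # a closed loop travels far but displaces nowhere
  th <- seq(0, 2 * pi, length.out = 61)
  loop <- tibble::tibble(
    t = t0() + (0:60) * 4 * 3600,
    x = 5000 * cos(th), y = 5000 * sin(th)
  )
  seg2 <- tibble::tibble(
    state = "exploratory",
    t_start = as.Date("2023-01-01"), t_end = as.Date("2023-01-11"),
    duration_days = 11L, displacement_km = 0
  )
  out2 <- summarize_states(seg2, loop, c(5000, 0))
  expect_gt(out2$path_km, 30)
  expect_lt(
    sqrt((loop$x[61] - loop$x[1])^2 + (loop$y[61] - loop$y[1])^2), 1e-6
  )
})
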