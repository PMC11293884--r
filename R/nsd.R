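#' Segmentation parameters
#'
#' The three canonical net-squared-displacement (NSD) shapes — excursion-and-
#' return, one-way departure, and post-departure plateau — are made
#' operational with these thresholds. Defaults were chosen so the shapes are
#' separable on simulated trajectories; all are tunable.
#'
#' @param natal_residency_min_days initial residency window used to estimate
#'   the natal range (default 30; residency "longer than a month").
#' @param natal_radius_quantile quantile of daily distances from the natal
#'   centroid defining the natal radius (default 0.95).
#' @param return_threshold NSD level, as a multiple of natal radius squared,
#'   below which the animal counts as inside the natal range (default 1).
#' @param away_min_days minimum consecutive days beyond threshold to count as
#'   having left (default 7).
#' @param plateau_cv_max maximum coefficient of variation of NSD over a
#'   sliding window to call home-ranging (default 0.15).
#' @param plateau_window_days sliding-window length for the plateau test
#'   (default 21).
#' @param transient_max_days home-ranging shorter than this is transient,
#'   longer is established (183 days, i.e. 6 months).
#' @param min_radius_m floor on the natal radius used in thresholds so a
#'   point-like natal range still yields a usable threshold (default 50 m).
#' @export
segmentation_params <- function(natal_residency_min_days = 30,
                                natal_radius_quantile = 0.95,
                                return_threshold = 1.0,
                                away_min_days = 7,
                                plateau_cv_max = 0.15,
                                plateau_window_days = 21,
                                transient_max_days = 183,
                                min_radius_m = 50) {
  p <- list(
    natal_residency_min_days = natal_residency_min_days,
    natal_radius_quantile = natal_radius_quantile,
    return_threshold = return_threshold,
    away_min_days = away_min_days,
    plateau_cv_max = plateau_cv_max,
    plateau_window_days = plateau_window_days,
    transient_max_days = transient_max_days,
    min_radius_m = min_radius_m
  )
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v > 0, TRUE)))
  structure(p, class = "segmentation_params")
}

# one representative fix per calendar day: the fix nearest local noon
daily_fixes <- function(fixes) {
  stopifnot(nrow(fixes) >= 1)
  day <- as.Date(fixes$t, tz = "UTC")
  secs <- as.numeric(fixes$t) - as.numeric(as.POSIXct(paste(day, "12:00:00"),
    tz = "UTC"
  ))
  ord <- order(day, abs(secs), fixes$t)
  f <- fixes[ord, , drop = FALSE]
  f <- f[!duplicated(day[ord]), , drop = FALSE]
  f$day <- as.Date(f$t, tz = "UTC")
  f[order(f$day), , drop = FALSE]
}

#' Daily net-squared displacement
#'
#' One GPS location per calendar day (the fix nearest local noon); NSD is the
#' squared Euclidean distance from `origin`, in km^2. Days without fixes are
#' absent, never interpolated.
#'
#' @param fixes tibble with `t, x, y` for one animal.
#' @param origin length-2 numeric, the natal-range center (m).
#' @return tibble with `day`, `x`, `y`, `nsd` (km^2).
#' @export
compute_nsd <- function(fixes, origin) {
  f <- daily_fixes(fixes)
  tibble::tibble(
    day = f$day, x = f$x, y = f$y,
    nsd = ((f$x - origin[1])^2 + (f$y - origin[2])^2) / 1e6
  )
}

#' Estimate the natal range from the initial residency window
#'
#' Origin = centroid of the daily fixes in the first
#' `natal_residency_min_days` days, extended day by day while the animal
#' stays inside the estimated radius; radius = the
#' `natal_radius_quantile` of daily distances from the origin. Residency is
#' required: if the net shift between the mean of the first five and last
#' five daily positions of the initial window exceeds 1.5x the radius
#' (monotone drift rather than home-ranging; the margin absorbs the sampling
#' noise of short positional means), the animal is flagged and excluded
#' downstream — mirroring the exclusion of individuals that never displayed
#' home-ranging around the capture site.
#'
#' @param fixes tibble with `t, x, y` for one animal.
#' @param params a [segmentation_params()].
#' @return list with `ok` (logical), `origin`, `radius_m`, `window_end`
#'   (last day used) and `reason` when flagged.
#' @export
estimate_natal_range <- function(fixes, params = segmentation_params()) {
  f <- daily_fixes(fixes)
  span <- as.integer(max(f$day) - min(f$day)) + 1L
  if (span < params$natal_residency_min_days) {
    return(list(
      ok = FALSE, origin = NULL, radius_m = NA_real_,
      window_end = NULL, reason = "insufficient data for residency window"
    ))
  }
  win_end <- min(f$day) + params$natal_residency_min_days - 1L
  w <- f[f$day <= win_end, , drop = FALSE]
  origin <- c(mean(w$x), mean(w$y))
  d <- sqrt((w$x - origin[1])^2 + (w$y - origin[2])^2)
  radius <- as.numeric(quantile(d, params$natal_radius_quantile))
  k <- min(5L, nrow(w))
  drift <- sqrt(
    (mean(utils::head(w$x, k)) - mean(utils::tail(w$x, k)))^2 +
      (mean(utils::head(w$y, k)) - mean(utils::tail(w$y, k)))^2
  )
  if (drift > 1.5 * max(radius, params$min_radius_m)) {
    return(list(
      ok = FALSE, origin = origin, radius_m = radius, window_end = win_end,
      reason = "no home-ranging plateau in residency window (monotone drift)"
    ))
  }
  # extend the window while the animal keeps returning to the estimated range
  thr <- max(radius, params$min_radius_m) * sqrt(params$return_threshold)
  rest <- f[f$day > win_end, , drop = FALSE]
  for (i in seq_len(nrow(rest))) {
    di <- sqrt((rest$x[i] - origin[1])^2 + (rest$y[i] - origin[2])^2)
    if (di > thr) break
    win_end <- rest$day[i]
  }
  w <- f[f$day <= win_end, , drop = FALSE]
  origin <- c(mean(w$x), mean(w$y))
  d <- sqrt((w$x - origin[1])^2 + (w$y - origin[2])^2)
  radius <- as.numeric(quantile(d, params$natal_radius_quantile))
  list(
    ok = TRUE, origin = origin, radius_m = radius, window_end = win_end,
    reason = NULL
  )
}

# Plateau detection with sharp boundaries. Core days: a day whose centered
# window of `window_days` has NSD coefficient of variation <= cv_max (the
# window must cover most of its nominal span, so gappy data cannot fake a
# plateau). Core runs are then extended outward day by day while the adjacent
# observation stays within 2*cv_max of the core mean — this recovers the
# plateau edges that a centered window necessarily misses (half a window at
# each end, including a plateau still ongoing when the record ends).
plateau_days <- function(day, nsd, window_days, cv_max) {
  n <- length(day)
  flag <- rep(FALSE, n)
  if (n < 5L) return(flag)
  dnum <- as.integer(day)
  half <- window_days / 2
  core <- rep(FALSE, n)
  for (i in seq_len(n)) {
    inwin <- abs(dnum - dnum[i]) <= half
    if (sum(inwin) < 5L) next
    if (diff(range(dnum[inwin])) < window_days * 0.6) next
    m <- mean(nsd[inwin])
    if (m <= 0 || sd(nsd[inwin]) / m <= cv_max) core[i] <- TRUE
  }
  if (!any(core)) return(flag)
  r <- rle(core)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i0 <- starts[k]
    i1 <- ends[k]
    m <- mean(nsd[i0:i1])
    tol <- 2 * cv_max * max(m, 1e-12)
    while (i0 > 1L && !flag[i0 - 1L] && abs(nsd[i0 - 1L] - m) <= tol) {
      i0 <- i0 - 1L
    }
    while (i1 < n && abs(nsd[i1 + 1L] - m) <= tol) i1 <- i1 + 1L
    flag[i0:i1] <- TRUE
  }
  flag
}

#' Classify dispersal states from daily NSD
#'
#' Scan of the daily NSD sequence against the natal threshold
#' (`return_threshold * radius^2`): days inside the range are natal; an
#' excursion of at least `away_min_days` that later re-enters is exploratory
#' (from its first day beyond threshold through the day before re-entry); an
#' excursion that never re-enters is a departure from its first day beyond
#' threshold; within post-departure data, maximal windows passing the NSD
#' plateau test around a new center are transient home ranges if shorter
#' than 6 months (183 days), established if at least 6 months — including
#' when the record ends while still in plateau. Ambiguity is resolved with
#' precedence natal > plateau > travel. Excursions shorter than
#' `away_min_days` count as natal-range noise.
#'
#' @param series result of [compute_nsd()].
#' @param radius_m natal radius from [estimate_natal_range()].
#' @param params a [segmentation_params()].
#' @return tibble of segments: `state, t_start, t_end, duration_days,
#'   displacement_km` (from origin at segment end); plus per-day labels in
#'   `attr(, "day_states")`.
#' @export
classify_states <- function(series, radius_m, params = segmentation_params()) {
  n <- nrow(series)
  thr <- params$return_threshold * (max(radius_m, params$min_radius_m) / 1000)^2
  inr <- series$nsd <= thr
  st <- rep(NA_character_, n)

  r <- rle(inr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dep_start <- NA_integer_
  for (k in seq_along(r$values)) {
    i0 <- starts[k]
    i1 <- ends[k]
    if (r$values[k]) {
      st[i0:i1] <- "natal"
    } else {
      span <- as.integer(series$day[i1] - series$day[i0]) + 1L
      if (span < params$away_min_days) {
        st[i0:i1] <- "natal" # short sally, still natal-range noise
      } else if (k < length(r$values)) {
        st[i0:i1] <- "exploratory" # re-enters later
      } else {
        dep_start <- i0 # never re-enters: departure onward
      }
    }
  }

  if (!is.na(dep_start)) {
    idx <- dep_start:n
    pl <- plateau_days(
      series$day[idx], series$nsd[idx],
      params$plateau_window_days, params$plateau_cv_max
    )
    lab <- ifelse(pl, "plateau", "departure")
    pr <- rle(lab)
    pe <- cumsum(pr$lengths)
    ps <- pe - pr$lengths + 1L
    for (k in seq_along(pr$values)) {
      sub <- idx[ps[k]:pe[k]]
      if (pr$values[k] == "departure") {
        st[sub] <- "departure"
      } else {
        dur <- as.integer(series$day[sub[length(sub)]] - series$day[sub[1]]) + 1L
        st[sub] <- if (dur >= params$transient_max_days) {
          "established"
        } else {
          "transient_home_range"
        }
      }
    }
  }

  runs <- rle(st)
  re <- cumsum(runs$lengths)
  rs <- re - runs$lengths + 1L
  seg <- tibble::tibble(
    state = runs$values,
    t_start = series$day[rs],
    t_end = series$day[re],
    duration_days = as.integer(series$day[re] - series$day[rs]) + 1L,
    displacement_km = sqrt(series$nsd[re])
  )
  attr(seg, "day_states") <- tibble::tibble(day = series$day, state = st)
  seg
}

#' Per-state movement summaries
#'
#' For each segment: duration, cumulative path length (sum of consecutive-fix
#' distances inside the segment) and straight-line displacement from the
#' natal origin to the segment end.
#'
#' @param segments result of [classify_states()].
#' @param fixes full-rate fixes tibble (`t, x, y`) for the animal.
#' @param origin natal origin (m).
#' @return `segments` with `path_km` added.
#' @export
summarize_states <- function(segments, fixes, origin) {
  ts <- as.Date(fixes$t, tz = "UTC")
  path <- numeric(nrow(segments))
  for (k in seq_len(nrow(segments))) {
    inseg <- ts >= segments$t_start[k] & ts <= segments$t_end[k]
    f <- fixes[inseg, , drop = FALSE]
    path[k] <- if (nrow(f) >= 2) {
      sum(sqrt(diff(f$x)^2 + diff(f$y)^2)) / 1000
    } else {
      0
    }
  }
  segments$path_km <- path
  segments
}

#' Segment one animal end to end
#'
#' Convenience wrapper: natal-range estimation, daily NSD, state
#' classification and summaries. Animals without a natal-range plateau are
#' returned flagged (`ok = FALSE`) and should be excluded downstream.
#'
#' @param fixes tibble with `t, x, y` for one animal.
#' @param params a [segmentation_params()].
#' @return list with `ok`, `natal` (origin/radius), `series`, `segments`.
#' @export
segment_animal <- function(fixes, params = segmentation_params()) {
  natal <- estimate_natal_range(fixes, params)
  if (!natal$ok) {
    return(list(ok = FALSE, natal = natal, series = NULL, segments = NULL))
  }
  series <- compute_nsd(fixes, natal$origin)
  seg <- classify_states(series, natal$radius_m, params)
  seg <- summarize_states(seg, fixes, natal$origin)
  list(ok = TRUE, natal = natal, series = series, segments = seg)
}
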