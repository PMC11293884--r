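#' Von Mises random deviates
#'
#' Best & Fisher (1979) rejection sampler; `kappa = 0` returns uniform angles.
#' Angles in radians on (-pi, pi], centered on `mu`.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-8) {
    return(wrap_angle(stats::runif(n, -pi, pi) + mu))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0L) {
      u3 <- stats::runif(k)
      th <- sign(u3 - 0.5) * acos(f[ok])
      out[(got + 1L):(got + k)] <- th
      got <- got + k
    }
  }
  wrap_angle(out + mu)
}

# wrap radians to (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

#' Fix-schedule configuration
#'
#' @param nominal_interval_min minutes between programmed fixes (default 240,
#'   a four-hour duty cycle).
#' @param jitter_sd_min SD of Gaussian timestamp jitter (min).
#' @param p_missed probability any one fix fails to record.
#' @param seed integer RNG seed used by [simulate_track()].
#' @export
fix_schedule <- function(nominal_interval_min = 240, jitter_sd_min = 0,
                         p_missed = 0, seed = NULL) {
  stopifnot(
    nominal_interval_min > 0, jitter_sd_min >= 0,
    p_missed >= 0, p_missed < 1
  )
  structure(
    list(
      nominal_interval_min = nominal_interval_min,
      jitter_sd_min = jitter_sd_min, p_missed = p_missed, seed = seed
    ),
    class = "fix_schedule"
  )
}

#' Generative movement/selection model for simulation
#'
#' The simulator draws `n_candidates` candidate steps from the gamma/von Mises
#' kernels at every time increment and picks one with probability proportional
#' to `exp(beta . z + attraction)`, where `z` are the stack's standardized
#' covariates at the candidate endpoint and the attraction term (active in
#' home-ranging states) penalizes endpoints beyond the state's radius from
#' its center. States are time-scheduled so ground-truth change points are
#' exact.
#'
#' @param beta named selection coefficients on standardized covariate layers.
#' @param gamma_shape,gamma_scale step-length kernel (scale in m).
#' @param vm_kappa turning-angle concentration.
#' @param state_schedule data frame with columns `state` (one of natal,
#'   exploratory, departure, transient_home_range, established, roam) and
#'   `duration_days`.
#' @param natal_center length-2 numeric (m), inside the raster extent.
#' @param natal_radius_m radius of the natal (and transient) range.
#' @param attract_strength log-weight penalty per meter beyond the state
#'   radius; also sets the strength of directed travel toward exploration
#'   waypoints and departure settlement points.
#' @param explore_dist_m waypoint distance for exploratory excursions
#'   (default a quarter of the domain size).
#' @param settle_dist_m settlement distance for departure (default 0.4 of the
#'   domain size).
#' @export
true_model <- function(beta, gamma_shape = 2, gamma_scale = 250, vm_kappa = 0.5,
                       state_schedule = data.frame(
                         state = "roam", duration_days = 30
                       ),
                       natal_center = NULL, natal_radius_m = 2000,
                       attract_strength = 0.004,
                       explore_dist_m = NULL, settle_dist_m = NULL) {
  stopifnot(
    gamma_shape > 0, gamma_scale > 0, vm_kappa >= 0,
    all(state_schedule$duration_days > 0)
  )
  structure(
    list(
      beta = beta, gamma_shape = gamma_shape, gamma_scale = gamma_scale,
      vm_kappa = vm_kappa, state_schedule = state_schedule,
      natal_center = natal_center, natal_radius_m = natal_radius_m,
      attract_strength = attract_strength,
      explore_dist_m = explore_dist_m, settle_dist_m = settle_dist_m
    ),
    class = "true_model"
  )
}

# draw a target point at roughly `dist` from `from`, at least `margin` inside
# the extent
draw_target <- function(from, dist, ext, margin) {
  for (i in 1:50) {
    th <- stats::runif(1, 0, 2 * pi)
    p <- from + dist * c(cos(th), sin(th))
    if (p[1] > ext["xmin"] + margin && p[1] < ext["xmax"] - margin &&
      p[2] > ext["ymin"] + margin && p[2] < ext["ymax"] - margin) {
      return(p)
    }
    dist <- dist * 0.95
  }
  c(
    mean(ext[c("xmin", "xmax")]),
    mean(ext[c("ymin", "ymax")])
  )
}

#' Simulate a GPS track from a known selection model
#'
#' Habitat-biased correlated random walk on a covariate stack. Candidate
#' endpoints falling outside the raster are redrawn (bounded retries); on
#' exhaustion the step is truncated at the boundary and counted in the
#' `truncated_steps` attribute. Timestamps follow the fix schedule with
#' optional jitter and dropped fixes. Each emitted fix carries its true
#' scheduled state, the ground truth for segmentation tests.
#'
#' @param stack a `cov_stack`.
#' @param model a [true_model()]; `names(model$beta)` must be usable layers.
#' @param sched a [fix_schedule()].
#' @param n_candidates candidate steps per increment (default 20, the same
#'   number used on the estimation side).
#' @param animal_id id string for the output.
#' @param t0 POSIXct start time (UTC).
#' @param seed RNG seed; default `sched$seed`.
#' @param wrap simulate on a periodic (toroidal) landscape: covariate lookups
#'   wrap modulo the extent, coordinates stay on the unbounded plane, and no
#'   boundary handling or containment is needed. Used for estimator
#'   validation; dispersal-geometry simulations keep the bounded landscape.
#' @return tibble with columns `animal_id, t, x, y, true_state`; attributes
#'   `truncated_steps`, `extent`, `cov_mean_used`, `cov_mean_candidates`.
#' @export
simulate_track <- function(stack, model, sched = fix_schedule(),
                           n_candidates = 20, animal_id = "A1",
                           t0 = as.POSIXct("2023-01-01 00:00:00", tz = "UTC"),
                           seed = sched$seed, wrap = FALSE) {
  ext <- c(
    xmin = stack$xmin, xmax = stack$xmin + stack$ncol * stack$cell_m,
    ymin = stack$ymin, ymax = stack$ymin + stack$nrow * stack$cell_m
  )
  bnames <- names(model$beta)
  if (!all(bnames %in% names(stack$layers))) {
    stop("beta names not in stack layers: ",
      paste(setdiff(bnames, names(stack$layers)), collapse = ", "))
  }
  center <- model$natal_center
  if (is.null(center)) {
    center <- c(mean(ext[c("xmin", "xmax")]), mean(ext[c("ymin", "ymax")]))
  }
  if (!wrap && (center[1] <= ext["xmin"] || center[1] >= ext["xmax"] ||
    center[2] <= ext["ymin"] || center[2] >= ext["ymax"])) {
    stop("natal_center outside raster extent")
  }
  domain <- min(ext["xmax"] - ext["xmin"], ext["ymax"] - ext["ymin"])
  explore_dist <- model$explore_dist_m %||% (0.25 * domain)
  settle_dist <- model$settle_dist_m %||% (0.4 * domain)
  margin <- 0.05 * domain

  # pre-standardized layers for fast lookup in the hot loop
  zlay <- lapply(bnames, function(nm) {
    (stack$layers[[nm]] - stack$center[[nm]]) / stack$scale[[nm]]
  })
  betav <- as.numeric(model$beta)
  nrw <- stack$nrow
  dt_s <- sched$nominal_interval_min * 60

  sched_states <- rep(
    model$state_schedule$state,
    times = round(model$state_schedule$duration_days * 86400 / dt_s)
  )
  n_steps <- length(sched_states)
  # split exploratory runs into outbound/return halves
  leg <- integer(n_steps)
  r <- rle(sched_states)
  pos <- cumsum(c(0L, r$lengths))
  for (i in seq_along(r$values)) {
    if (r$values[i] == "exploratory") {
      half <- r$lengths[i] %/% 2L
      leg[(pos[i] + 1L):(pos[i] + half)] <- 1L # outbound
      leg[(pos[i] + half + 1L):pos[i + 1L]] <- 2L # homing
    }
  }

  with_seed(seed, {
    sl_all <- matrix(
      stats::rgamma(n_steps * n_candidates, shape = model$gamma_shape,
        scale = model$gamma_scale),
      n_steps, n_candidates
    )
    ta_all <- matrix(
      rvonmises(n_steps * n_candidates, 0, model$vm_kappa),
      n_steps, n_candidates
    )
    xs <- numeric(n_steps + 1L)
    ys <- numeric(n_steps + 1L)
    xs[1] <- center[1]
    ys[1] <- center[2]
    bearing <- stats::runif(1, -pi, pi)
    truncated <- 0L
    cum_used <- cum_cand <- numeric(length(bnames))
    prev_state <- ""
    target <- center
    radius <- model$natal_radius_m
    attract <- TRUE

    for (i in seq_len(n_steps)) {
      st <- sched_states[i]
      st_key <- paste0(st, leg[i])
      if (st_key != prev_state) {
        if (st == "natal") {
          target <- center; radius <- model$natal_radius_m; attract <- TRUE
        } else if (st == "exploratory" && leg[i] == 1L) {
          target <- draw_target(c(xs[i], ys[i]), explore_dist, ext, margin)
          radius <- model$natal_radius_m; attract <- TRUE
        } else if (st == "exploratory") {
          target <- center; radius <- model$natal_radius_m; attract <- TRUE
        } else if (st == "departure") {
          target <- draw_target(center, settle_dist, ext, margin)
          radius <- model$natal_radius_m; attract <- TRUE
        } else if (st %in% c("transient_home_range", "established")) {
          target <- c(xs[i], ys[i]); radius <- model$natal_radius_m
          attract <- TRUE
        } else {
          attract <- FALSE
        }
        prev_state <- st_key
      }
      sl <- sl_all[i, ]
      ta <- ta_all[i, ]
      br <- bearing + ta
      ex <- xs[i] + sl * cos(br)
      ey <- ys[i] + sl * sin(br)
      if (!wrap) {
        # redraw candidates that leave the raster
        for (try in 1:10) {
          out <- ex <= ext["xmin"] | ex >= ext["xmax"] |
            ey <= ext["ymin"] | ey >= ext["ymax"]
          if (!any(out)) break
          k <- sum(out)
          sl[out] <- stats::rgamma(k, shape = model$gamma_shape,
            scale = model$gamma_scale)
          ta[out] <- rvonmises(k, 0, model$vm_kappa)
          br <- bearing + ta
          ex[out] <- xs[i] + sl[out] * cos(br[out])
          ey[out] <- ys[i] + sl[out] * sin(br[out])
        }
        out <- ex <= ext["xmin"] | ex >= ext["xmax"] |
          ey <= ext["ymin"] | ey >= ext["ymax"]
        if (any(out)) {
          truncated <- truncated + sum(out)
          ex <- pmin(pmax(ex, ext["xmin"] + stack$cell_m / 2),
            ext["xmax"] - stack$cell_m / 2)
          ey <- pmin(pmax(ey, ext["ymin"] + stack$cell_m / 2),
            ext["ymax"] - stack$cell_m / 2)
        }
      }
      col <- floor((ex - stack$xmin) / stack$cell_m) + 1L
      row <- floor((ey - stack$ymin) / stack$cell_m) + 1L
      if (wrap) {
        col <- ((col - 1L) %% stack$ncol) + 1L
        row <- ((row - 1L) %% nrw) + 1L
      }
      idx <- (col - 1L) * nrw + row
      w <- numeric(n_candidates)
      for (k in seq_along(zlay)) {
        zk <- zlay[[k]][idx]
        w <- w + betav[k] * zk
        cum_cand[k] <- cum_cand[k] + mean(zk)
      }
      if (attract) {
        dtar <- sqrt((ex - target[1])^2 + (ey - target[2])^2)
        w <- w - model$attract_strength * pmax(0, dtar - radius)
      }
      w <- exp(w - max(w))
      j <- sample.int(n_candidates, 1L, prob = w)
      for (k in seq_along(zlay)) cum_used[k] <- cum_used[k] + zlay[[k]][idx[j]]
      xs[i + 1L] <- ex[j]
      ys[i + 1L] <- ey[j]
      bearing <- atan2(ys[i + 1L] - ys[i], xs[i + 1L] - xs[i])
    }

    tt <- t0 + (0:n_steps) * dt_s
    if (sched$jitter_sd_min > 0) {
      tt <- tt + round(stats::rnorm(n_steps + 1L, 0, sched$jitter_sd_min * 60))
    }
    keep <- stats::runif(n_steps + 1L) >= sched$p_missed
    keep[1] <- TRUE
    trk <- tibble::tibble(
      animal_id = animal_id,
      t = tt[keep],
      x = xs[keep],
      y = ys[keep],
      true_state = c(sched_states[1], sched_states)[keep]
    )
    attr(trk, "truncated_steps") <- truncated
    attr(trk, "extent") <- ext
    if (n_steps > 0) {
      attr(trk, "cov_mean_used") <- setNames(cum_used / n_steps, bnames)
      attr(trk, "cov_mean_candidates") <- setNames(cum_cand / n_steps, bnames)
    }
    trk
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inject a stationary (kill-site-like) fix cluster into a track
#'
#' Inserts `n_fixes` fixes confined within `radius_m` of `center`, spanning
#' `duration_h`, at the track's midpoint (or at `at_time`); later fixes are
#' time-shifted by the cluster duration so the fix schedule stays valid. The
#' input track is not modified. Injected fixes carry `true_state =
#' "kill_site"`.
#'
#' @param track tibble with `animal_id, t, x, y` (and optionally `true_state`).
#' @param center length-2 numeric; must lie inside the track's raster extent
#'   when the track carries one (simulated tracks do).
#' @param radius_m maximal distance of injected fixes from `center`.
#' @param n_fixes number of injected fixes (>= 1).
#' @param duration_h time span of the injected run (h).
#' @param at_time POSIXct insertion time; default the track midpoint.
#' @param seed RNG seed for the fix placement.
#' @return the augmented track; tracks without a `true_state` column gain one
#'   (`NA` for the original fixes).
#' @export
inject_cluster <- function(track, center, radius_m, n_fixes, duration_h,
                           at_time = NULL, seed = NULL) {
  stopifnot(n_fixes >= 1, duration_h > 0, radius_m >= 0)
  ext <- attr(track, "extent")
  if (!is.null(ext)) {
    if (center[1] <= ext["xmin"] || center[1] >= ext["xmax"] ||
      center[2] <= ext["ymin"] || center[2] >= ext["ymax"]) {
      stop("cluster center outside raster extent")
    }
  }
  if (is.null(at_time)) at_time <- track$t[ceiling(nrow(track) / 2)]
  i_ins <- max(which(track$t <= at_time))
  with_seed(seed, {
    # uniform in the disc of radius radius_m
    rr <- radius_m * sqrt(stats::runif(n_fixes))
    th <- stats::runif(n_fixes, 0, 2 * pi)
    gap <- if (i_ins < nrow(track)) {
      as.numeric(difftime(track$t[i_ins + 1L], track$t[i_ins], units = "secs"))
    } else {
      duration_h * 3600 / max(1, n_fixes)
    }
    ct <- track$t[i_ins] + gap +
      seq(0, duration_h * 3600, length.out = max(2L, n_fixes))[seq_len(n_fixes)]
    clus <- tibble::tibble(
      animal_id = track$animal_id[1],
      t = ct,
      x = center[1] + rr * cos(th),
      y = center[2] + rr * sin(th),
      true_state = "kill_site"
    )
    shift <- duration_h * 3600 + gap
    after <- track[seq_len(nrow(track)) > i_ins, , drop = FALSE]
    after$t <- after$t + shift
    out <- dplyr::bind_rows(
      track[seq_len(i_ins), , drop = FALSE],
      clus, after
    )
    attr(out, "extent") <- ext
    out
  })
}
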