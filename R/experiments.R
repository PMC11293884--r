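#' @importFrom dplyr %>%
#' @importFrom dplyr .data
NULL

#' Default validation landscape
#'
#' A moderate synthetic landscape used by the package's validation
#' experiments: square domain with all six cover classes present. Cell size
#' defaults to 100 m (coarser than the 30 m analysis grid) so the distance
#' transforms and long simulated walks stay light; the covariate gradients it
#' creates are what the estimator sees, not the grid resolution.
#'
#' @param extent_m domain side (m).
#' @param cell_m cell size (m).
#' @param seed RNG seed.
#' @export
validation_landscape <- function(extent_m = 24000, cell_m = 100, seed = 1L) {
  cfg <- landscape_config(
    extent_m = extent_m, cell_m = cell_m,
    patch_density = c(
      forest = 0.6, shrub = 0.6, water = 0.15,
      hay_crop = 0.15, developed = 0.15, road4wd = 0.02
    ),
    elevation_relief_m = 600,
    patch_radius_m = 5 * cell_m,
    seed = seed
  )
  build_covariates(generate_landscape(cfg))
}

#' Simulate one animal's matched step strata under known selection
#'
#' Full generative-to-strata path: a free-roaming habitat-biased walk under
#' `beta_true` on a periodic (toroidal) landscape — boundaryless, so the
#' generative process is exactly the habitat-tilted kernel model the
#' conditional logistic estimator targets, with no containment term to
#' confound it — regularized with [resample_track()], used steps built, a
#' tentative kernel fitted from the used steps, 20 random steps matched per
#' used step and covariates attached. Each animal starts at a random point so
#' animals sample different parts of the landscape. Strata beyond `n_strata`
#' are discarded so every animal contributes the same amount of data.
#'
#' @param stack a `cov_stack`.
#' @param beta_true named true coefficients (standardized scale).
#' @param n_strata strata to keep per animal.
#' @param n_random available steps per stratum on the estimation side.
#' @param gen_candidates candidate steps per increment on the generative
#'   side. The default (100) is deliberately larger than `n_random`: the
#'   finite candidate set is a discretization of the continuous
#'   habitat-tilted choice model that conditional logistic regression
#'   estimates, and with only ~20 candidates the generated process is a
#'   measurably coarser model (selection coefficients attenuate by a few
#'   percent); 100 candidates makes the generative model match the estimand.
#' @param seed RNG seed.
#' @param animal_id id string.
#' @param interval_min fix interval (min).
#' @return list with `strata` (tibble), `kernel`, `track`.
#' @export
simulate_animal_strata <- function(stack, beta_true, n_strata = 300,
                                   n_random = 20, gen_candidates = 100,
                                   seed = 1L,
                                   animal_id = "A1", interval_min = 240) {
  n_steps <- ceiling(n_strata * 1.1) + 5
  dur_days <- n_steps * interval_min / 1440
  domain <- min(stack$ncol, stack$nrow) * stack$cell_m
  start <- with_seed(seed + 17L, stats::runif(2, 0, domain))
  model <- true_model(
    beta = beta_true,
    state_schedule = data.frame(state = "roam", duration_days = dur_days),
    natal_center = start
  )
  track <- simulate_track(stack, model,
    sched = fix_schedule(nominal_interval_min = interval_min),
    n_candidates = gen_candidates, animal_id = animal_id, seed = seed,
    wrap = TRUE
  )
  bursts <- resample_track(track,
    target_interval_min = interval_min, tolerance_min = 10
  )
  steps <- steps_from_bursts(bursts)
  kernel <- fit_tentative_kernel(steps$sl, steps$ta)
  strata <- generate_random_steps(steps, kernel,
    n_random = n_random, seed = seed + 1L
  )
  strata <- add_step_covariates(strata, stack, wrap = TRUE)
  keep <- sort(unique(strata$stratum_id))
  keep <- keep[seq_len(min(n_strata, length(keep)))]
  list(
    strata = strata[strata$stratum_id %in% keep, , drop = FALSE],
    kernel = kernel, track = track
  )
}

#' Simulate and fit one site
#'
#' `n_animals` independent animals simulated under the same true
#' coefficients, each fitted by conditional logistic regression (habitat
#' terms plus `log_sl` and `cos_ta`), then pooled by inverse variance.
#'
#' @param stack a `cov_stack`.
#' @param beta_true named true coefficients.
#' @param n_animals animals per site.
#' @param n_strata strata per animal.
#' @param site,state labels for the pooled output.
#' @param seed RNG seed.
#' @return list with `pooled` (tibble), `fits` (tidy per-term rows).
#' @export
run_site <- function(stack, beta_true, n_animals = 10, n_strata = 300,
                     site = "A", state = "all", seed = 1L) {
  spec <- issa_spec(habitat_terms = names(beta_true))
  rows <- vector("list", n_animals)
  for (a in seq_len(n_animals)) {
    sim <- simulate_animal_strata(stack, beta_true,
      n_strata = n_strata,
      seed = seed * 1000L + a, animal_id = sprintf("%s%02d", site, a)
    )
    fit <- fit_clogit(sim$strata, spec, min_strata = 30)
    rows[[a]] <- tidy_issa_fit(fit, sprintf("%s%02d", site, a), site, state)
  }
  fits <- dplyr::bind_rows(rows)
  list(pooled = pool_fits(fits), fits = fits)
}

#' Parameter-recovery experiment (single site)
#'
#' Replicates of a 10-animal site simulated under known coefficients
#' (`dist_forest_log = -0.5`, `tri = +0.25`, `dist_developed_log = +0.3`);
#' each replicate is pushed through the full estimation path and pooled.
#' Reports per-term bias, the per-replicate 2-pooled-SE check and empirical
#' 95% CI coverage (pooled over the three terms, per-term also returned).
#'
#' @param n_reps replicates (default 100).
#' @param n_animals,n_strata site size per replicate.
#' @param seed RNG seed (also seeds the landscape).
#' @param stack optional pre-built `cov_stack`.
#' @return list with `truth`, `per_rep` (tibble), `coverage_overall`,
#'   `coverage_by_term`, `within_2se_rate`, `mean_beta`.
#' @export
run_recovery_experiment <- function(n_reps = 100, n_animals = 10,
                                    n_strata = 300, seed = 1L, stack = NULL) {
  truth <- c(dist_forest_log = -0.5, tri = 0.25, dist_developed_log = 0.3)
  if (is.null(stack)) stack <- validation_landscape(seed = seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    res <- run_site(stack, truth,
      n_animals = n_animals, n_strata = n_strata,
      site = "A", seed = seed + r * 131L
    )
    p <- res$pooled[res$pooled$term %in% names(truth), , drop = FALSE]
    p$truth <- truth[p$term]
    p$rep <- r
    p$covered <- p$ci_low <= p$truth & p$truth <= p$ci_high
    p$within_2se <- abs(p$beta_bar - p$truth) <= 2 * p$se_bar
    reps[[r]] <- p
  }
  per_rep <- dplyr::bind_rows(reps)
  by_term <- per_rep %>%
    dplyr::group_by(.data$term) %>%
    dplyr::summarise(
      coverage = mean(.data$covered),
      within_2se = mean(.data$within_2se),
      mean_beta = mean(.data$beta_bar),
      truth = .data$truth[1],
      .groups = "drop"
    )
  list(
    truth = truth,
    per_rep = per_rep,
    coverage_overall = mean(per_rep$covered),
    coverage_by_term = by_term,
    within_2se_rate = mean(per_rep$within_2se),
    mean_beta = setNames(by_term$mean_beta, by_term$term)
  )
}

#' Two-site contrast power experiment
#'
#' Site A simulated with `dist_developed_log = +0.4` (avoidance of proximity
#' to development), site B with 0, all else equal; a replicate succeeds when
#' [compare_sites()] flags the development term significant at A and not at
#' B.
#'
#' @param n_reps replicates (default 50).
#' @param n_animals,n_strata site size per replicate.
#' @param seed RNG seed.
#' @param stack optional pre-built `cov_stack`.
#' @return list with `power`, `per_rep` (tibble).
#' @export
run_twosite_power <- function(n_reps = 50, n_animals = 10, n_strata = 300,
                              seed = 1L, stack = NULL) {
  base <- c(dist_forest_log = -0.5, tri = 0.25)
  beta_a <- c(base, dist_developed_log = 0.4)
  beta_b <- c(base, dist_developed_log = 0)
  if (is.null(stack)) stack <- validation_landscape(seed = seed)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sa <- run_site(stack, beta_a,
      n_animals = n_animals, n_strata = n_strata,
      site = "A", seed = seed + r * 613L
    )
    sb <- run_site(stack, beta_b,
      n_animals = n_animals, n_strata = n_strata,
      site = "B", seed = seed + r * 613L + 307L
    )
    cmp <- compare_sites(sa$pooled, sb$pooled)
    row <- cmp[cmp$term == "dist_developed_log", , drop = FALSE]
    out[[r]] <- tibble::tibble(
      rep = r,
      beta_a = row$beta_bar_a, beta_b = row$beta_bar_b,
      sig_a = isTRUE_v(row$significant_a), sig_b = isTRUE_v(row$significant_b),
      success = isTRUE_v(row$significant_a) & !isTRUE_v(row$significant_b)
    )
  }
  per_rep <- dplyr::bind_rows(out)
  list(power = mean(per_rep$success), per_rep = per_rep)
}

#' Null-calibration experiment
#'
#' Animals simulated with all selection coefficients zero; per-term Wald 95%
#' significance rates should sit near the nominal 5%.
#'
#' @param n_reps replicates (default 200).
#' @param n_strata strata per replicate (one animal each).
#' @param seed RNG seed.
#' @param stack optional pre-built `cov_stack`.
#' @return list with `rate_by_term`, `rate_overall`, `n_reps`.
#' @export
run_null_calibration <- function(n_reps = 200, n_strata = 150, seed = 1L,
                                 stack = NULL) {
  truth <- c(dist_forest_log = 0, tri = 0, dist_developed_log = 0)
  if (is.null(stack)) stack <- validation_landscape(seed = seed)
  spec <- issa_spec(habitat_terms = names(truth))
  hits <- matrix(NA, n_reps, length(truth) + 2L)
  for (r in seq_len(n_reps)) {
    sim <- simulate_animal_strata(stack, truth,
      n_strata = n_strata,
      seed = seed + r * 271L, animal_id = "N1"
    )
    fit <- fit_clogit(sim$strata, spec, min_strata = 30)
    zst <- abs(fit$beta / fit$se)
    hits[r, seq_along(zst)] <- zst > stats::qnorm(0.975)
  }
  cn <- c(names(truth), "log_sl", "cos_ta")
  colnames(hits) <- cn
  rate <- colMeans(hits, na.rm = TRUE)
  list(
    rate_by_term = rate[names(truth)],
    rate_overall = mean(hits[, names(truth)], na.rm = TRUE),
    n_reps = n_reps
  )
}

#' Permutation null for the conditional logistic fit
#'
#' The used-step label is shuffled within every stratum and the model refitted;
#' over shuffles the coefficients must center on zero regardless of the true
#' selection in the data.
#'
#' @param strata a strata tibble (e.g. from [simulate_animal_strata()]).
#' @param spec an [issa_spec()].
#' @param n_shuffles shuffles (default 200).
#' @param seed RNG seed.
#' @return list with `mean_beta` (named), `betas` (matrix).
#' @export
run_permutation_null <- function(strata, spec, n_shuffles = 200, seed = 1L) {
  with_seed(seed, {
    ids <- unique(strata$stratum_id)
    betas <- NULL
    for (s in seq_len(n_shuffles)) {
      sh <- strata
      # draw the pseudo-used row uniformly within each stratum
      pick <- stats::ave(seq_len(nrow(sh)), sh$stratum_id, FUN = function(i) {
        j <- i[sample.int(length(i), 1L)]
        as.integer(i == j)
      })
      sh$case <- as.integer(pick)
      fit <- fit_clogit(sh, spec, min_strata = 2)
      if (is.null(betas)) {
        betas <- matrix(NA_real_, n_shuffles, length(fit$beta),
          dimnames = list(NULL, names(fit$beta))
        )
      }
      betas[s, names(fit$beta)] <- fit$beta
    }
    list(mean_beta = colMeans(betas, na.rm = TRUE), betas = betas)
  })
}

#' Default state schedule for dispersal simulations
#'
#' Durations sized to the walk's directed-travel speed (roughly 3 km/day at
#' the default kernel and attraction) so the scheduled change points line up
#' with the canonical NSD shapes: natal residency, an exploratory excursion
#' with return, renewed residency, a one-way departure, and a transient home
#' range held to collar drop.
#'
#' @param natal_days,explore_days,home_days,departure_days,transient_days
#'   state durations (days).
#' @export
dispersal_schedule <- function(natal_days = 35, explore_days = 12,
                               home_days = 14, departure_days = 11,
                               transient_days = 60) {
  data.frame(
    state = c(
      "natal", "exploratory", "natal", "departure", "transient_home_range"
    ),
    duration_days = c(
      natal_days, explore_days, home_days, departure_days, transient_days
    )
  )
}

#' Segmentation-recovery experiment
#'
#' Scheduled-state animals simulated on a synthetic landscape, segmented with
#' the NSD classifier, and scored against ground truth: per-day state
#' accuracy and mean absolute change-point displacement (days).
#'
#' @param n_animals animals (default 20).
#' @param seed RNG seed.
#' @param stack optional `cov_stack` (default a coarse validation landscape
#'   big enough for dispersal distances).
#' @param params a [segmentation_params()].
#' @return list with `accuracy`, `changepoint_mae_days`, `per_animal`.
#' @export
run_segmentation_experiment <- function(n_animals = 20, seed = 1L,
                                        stack = NULL,
                                        params = segmentation_params()) {
  if (is.null(stack)) {
    stack <- validation_landscape(extent_m = 90000, cell_m = 300, seed = seed)
  }
  domain <- min(stack$ncol, stack$nrow) * stack$cell_m
  res <- vector("list", n_animals)
  for (a in seq_len(n_animals)) {
    model <- true_model(
      beta = c(dist_forest_log = -0.3, tri = 0.2),
      state_schedule = dispersal_schedule(),
      natal_center = c(domain / 2, domain / 2),
      natal_radius_m = 2000,
      explore_dist_m = 21000,
      settle_dist_m = 40000
    )
    track <- simulate_track(stack, model,
      sched = fix_schedule(nominal_interval_min = 240),
      animal_id = sprintf("S%02d", a), seed = seed + a * 97L
    )
    seg <- segment_animal(track, params)
    if (!seg$ok) {
      res[[a]] <- tibble::tibble(
        animal_id = sprintf("S%02d", a), accuracy = NA_real_,
        cp_mae = NA_real_, flagged = TRUE
      )
      next
    }
    truth_day <- daily_fixes(track)[, c("day", "true_state")]
    pred_day <- attr(seg$segments, "day_states")
    m <- dplyr::inner_join(truth_day, pred_day, by = "day")
    acc <- mean(m$true_state == m$state)
    cp_true <- m$day[which(m$true_state[-1] != m$true_state[-nrow(m)]) + 1L]
    cp_pred <- m$day[which(m$state[-1] != m$state[-nrow(m)]) + 1L]
    cp_mae <- if (length(cp_true) && length(cp_pred)) {
      mean(vapply(
        cp_true,
        function(d) min(abs(as.integer(d - cp_pred))), 0
      ))
    } else {
      NA_real_
    }
    res[[a]] <- tibble::tibble(
      animal_id = sprintf("S%02d", a), accuracy = acc,
      cp_mae = cp_mae, flagged = FALSE
    )
  }
  per_animal <- dplyr::bind_rows(res)
  list(
    accuracy = mean(per_animal$accuracy, na.rm = TRUE),
    changepoint_mae_days = mean(per_animal$cp_mae, na.rm = TRUE),
    per_animal = per_animal
  )
}

#' Brute-force grid-search oracle for the conditional logistic likelihood
#'
#' Hierarchical coordinate grid over the conditional log-likelihood
#' (derivative-free, independent of the Newton fitting path), refined down to
#' `final_step`. Intended for toy instances (<= 2 coefficients, <= 10
#' strata).
#'
#' @param strata strata tibble.
#' @param spec an [issa_spec()].
#' @param lower,upper search box per coefficient.
#' @param final_step terminal grid resolution (default 1e-4).
#' @return named numeric vector of grid-optimal coefficients.
#' @export
clogit_grid_search <- function(strata, spec, lower = -8, upper = 8,
                               final_step = 1e-5) {
  strata <- strata[order(strata$stratum_id, -strata$case), , drop = FALSE]
  X <- build_design(strata, spec)
  gs <- clogit_groups(strata$stratum_id, strata$case)
  k <- ncol(X)
  stopifnot(k <= 2)
  ll_at <- function(b) clogit_loglik(b, X, gs)$ll
  lo <- rep(lower, k)
  hi <- rep(upper, k)
  step <- (hi[1] - lo[1]) / 40
  best <- rep(0, k)
  while (step > final_step / 2) {
    grids <- lapply(seq_len(k), function(j) seq(lo[j], hi[j], by = step))
    if (k == 1L) {
      vals <- vapply(grids[[1]], function(b) ll_at(b), 0)
      best <- grids[[1]][which.max(vals)]
    } else {
      pts <- as.matrix(expand.grid(grids[[1]], grids[[2]]))
      vals <- apply(pts, 1, ll_at)
      best <- pts[which.max(vals), ]
    }
    lo <- best - 2 * step
    hi <- best + 2 * step
    step <- step / 10
  }
  setNames(as.numeric(best), colnames(X))
}
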