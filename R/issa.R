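#' Fit the tentative movement kernel
#'
#' Gamma step-length parameters by maximum likelihood (zero step lengths —
#' stationary fixes that survived cluster removal — are replaced by 2.5 m,
#' half the 5 m GPS precision floor, so the gamma support is respected) and
#' von Mises turning-angle concentration by maximum likelihood with the mean
#' direction fixed at zero (solved from the Bessel-function ratio
#' `A1(kappa) = mean(cos(ta))`).
#'
#' @param sl used step lengths (m).
#' @param ta used turning angles (radians); `NA` entries (first step of a
#'   burst) are dropped.
#' @param zero_floor_m replacement for zero step lengths.
#' @return a list of class `movement_kernel` with `gamma_shape`,
#'   `gamma_scale`, `vm_kappa`, `vm_mu = 0`, `n_steps`.
#' @export
fit_tentative_kernel <- function(sl, ta, zero_floor_m = 2.5) {
  sl <- sl[is.finite(sl)]
  if (length(sl) == 0L || all(sl <= 0)) stop("no positive step lengths")
  if (length(sl) < 30L) {
    warning("fewer than 30 used steps; kernel estimates will be unstable")
  }
  sl[sl <= 0] <- zero_floor_m
  fit <- tryCatch(
    MASS::fitdistr(sl, "gamma", lower = c(1e-8, 1e-12)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # method-of-moments fallback for pathological samples
    m <- mean(sl)
    v <- stats::var(sl)
    shape <- m^2 / v
    rate <- m / v
  } else {
    shape <- unname(fit$estimate["shape"])
    rate <- unname(fit$estimate["rate"])
  }
  ta <- ta[is.finite(ta)]
  kappa <- if (length(ta) == 0L) 0 else vm_kappa_mle(mean(cos(ta)))
  structure(
    list(
      gamma_shape = shape, gamma_scale = 1 / rate,
      vm_kappa = kappa, vm_mu = 0, n_steps = length(sl)
    ),
    class = "movement_kernel"
  )
}

# A1(kappa) = I1(kappa)/I0(kappa); exponential scaling cancels in the ratio
vm_A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# maximum-likelihood kappa for a von Mises sample with mu = 0, from
# Rbar = mean(cos(theta)); Rbar <= 0 gives kappa = 0 (no concentration)
vm_kappa_mle <- function(rbar, kappa_max = 1e5) {
  if (!is.finite(rbar) || rbar <= 0) return(0)
  if (rbar >= vm_A1(kappa_max)) return(kappa_max)
  stats::uniroot(
    function(k) vm_A1(k) - rbar,
    interval = c(1e-8, kappa_max), tol = 1e-10
  )$root
}

#' Build used steps from regular bursts
#'
#' Consecutive fixes within a burst define steps; turning angles need the
#' previous step's bearing, so the first step of each burst has `ta = NA`
#' (such strata are dropped at stratum assembly — simpler and unbiased).
#'
#' @param fixes tibble with `animal_id, burst_id, t, x, y`, time-sorted.
#' @return tibble of used steps: `animal_id, burst_id, t_start, t_end,
#'   x_start, y_start, x_end, y_end, sl, bearing, ta`.
#' @export
steps_from_bursts <- function(fixes) {
  out <- lapply(split(seq_len(nrow(fixes)), fixes$burst_id), function(idx) {
    f <- fixes[idx, , drop = FALSE]
    n <- nrow(f)
    if (n < 2L) return(NULL)
    dx <- diff(f$x)
    dy <- diff(f$y)
    bearing <- atan2(dy, dx)
    tibble::tibble(
      animal_id = f$animal_id[-n],
      burst_id = f$burst_id[-n],
      t_start = f$t[-n], t_end = f$t[-1],
      x_start = f$x[-n], y_start = f$y[-n],
      x_end = f$x[-1], y_end = f$y[-1],
      sl = sqrt(dx^2 + dy^2),
      bearing = bearing,
      ta = c(NA_real_, wrap_angle(diff(bearing)))
    )
  })
  dplyr::bind_rows(out)
}

#' Generate matched random (available) steps
#'
#' For every used step with a defined turning angle, `n_random` available
#' steps share the start point and time; their lengths are drawn from the
#' tentative gamma kernel and their turning angles from the von Mises kernel,
#' applied relative to the incoming bearing; endpoints by planar dead
#' reckoning. Fixed seed gives identical strata.
#'
#' @param steps result of [steps_from_bursts()].
#' @param kernel a `movement_kernel` from [fit_tentative_kernel()].
#' @param n_random available steps per stratum (default 20).
#' @param seed RNG seed.
#' @return tibble of used + available steps in matched strata: columns of
#'   `steps` plus `stratum_id` and `case` (1 used, 0 available).
#' @export
generate_random_steps <- function(steps, kernel, n_random = 20, seed = NULL) {
  stopifnot(n_random >= 1)
  used <- steps[is.finite(steps$ta), , drop = FALSE]
  n <- nrow(used)
  if (n == 0L) stop("no steps with defined turning angle")
  used$stratum_id <- seq_len(n)
  used$case <- 1L
  with_seed(seed, {
    m <- n * n_random
    sl <- stats::rgamma(m, shape = kernel$gamma_shape, scale = kernel$gamma_scale)
    ta <- rvonmises(m, kernel$vm_mu, kernel$vm_kappa)
    idx <- rep(seq_len(n), each = n_random)
    bearing_in <- (used$bearing - used$ta)[idx] # incoming bearing
    br <- bearing_in + ta
    avail <- tibble::tibble(
      animal_id = used$animal_id[idx],
      burst_id = used$burst_id[idx],
      t_start = used$t_start[idx], t_end = used$t_end[idx],
      x_start = used$x_start[idx], y_start = used$y_start[idx],
      x_end = used$x_start[idx] + sl * cos(br),
      y_end = used$y_start[idx] + sl * sin(br),
      sl = sl, bearing = wrap_angle(br), ta = ta,
      stratum_id = idx, case = 0L
    )
    out <- dplyr::bind_rows(used, avail)
    dplyr::arrange(out, .data$stratum_id, dplyr::desc(.data$case))
  })
}

#' Attach covariates to step strata
#'
#' End-point values of the habitat layers (selection terms) and start-point
#' values of the anthropogenic layers (movement-interaction terms, suffixed
#' `_start`). Strata with any missing value (off-raster endpoint) are dropped
#' whole.
#'
#' @param strata result of [generate_random_steps()].
#' @param stack a `cov_stack`.
#' @param habitat_layers end-point layers; default all usable layers.
#' @param anthro_layers start-point layers for interactions; default the
#'   stack's anthropogenic layers.
#' @param standardized z-score with the stack's stored mean/SD (default TRUE).
#' @param wrap periodic-landscape extraction (see [extract_at()]).
#' @export
add_step_covariates <- function(strata, stack,
                                habitat_layers = usable_layers(stack),
                                anthro_layers = stack$anthro_layers,
                                standardized = TRUE, wrap = FALSE) {
  ends <- extract_at(stack, strata$x_end, strata$y_end,
    layers = habitat_layers, standardized = standardized, wrap = wrap
  )
  out <- dplyr::bind_cols(strata, ends)
  if (length(anthro_layers)) {
    starts <- extract_at(stack, strata$x_start, strata$y_start,
      layers = anthro_layers, standardized = standardized, wrap = wrap
    )
    names(starts) <- paste0(names(starts), "_start")
    out <- dplyr::bind_cols(out, starts)
  }
  cov_cols <- c(habitat_layers, if (length(anthro_layers)) {
    paste0(anthro_layers, "_start")
  })
  bad <- !stats::complete.cases(out[, cov_cols, drop = FALSE])
  bad_strata <- unique(out$stratum_id[bad])
  out[!(out$stratum_id %in% bad_strata), , drop = FALSE]
}

#' Model specification for the global iSSA model
#'
#' Habitat terms enter as end-point covariates; movement terms as `log_sl`
#' and `cos_ta` (the iSSA-standard transforms, matching the gamma shape and
#' von Mises concentration adjustments); interactions couple the movement
#' terms with start-point anthropogenic covariates.
#'
#' @param habitat_terms end-point covariate names.
#' @param movement_terms subset of `c("log_sl", "cos_ta")` (also accepts
#'   `"sl"` for a scale adjustment).
#' @param interaction_anthro anthropogenic covariates interacted with the
#'   movement terms (start-point values); default none.
#' @export
issa_spec <- function(habitat_terms,
                      movement_terms = c("log_sl", "cos_ta"),
                      interaction_anthro = character(0)) {
  structure(
    list(
      habitat_terms = habitat_terms,
      movement_terms = movement_terms,
      interaction_anthro = interaction_anthro
    ),
    class = "issa_spec"
  )
}

# design matrix for the conditional logistic model
build_design <- function(strata, spec, zero_floor_m = 2.5) {
  sl <- pmax(strata$sl, zero_floor_m)
  base <- list()
  for (nm in spec$habitat_terms) base[[nm]] <- strata[[nm]]
  if ("log_sl" %in% spec$movement_terms) base$log_sl <- log(sl)
  if ("sl" %in% spec$movement_terms) base$sl <- sl
  if ("cos_ta" %in% spec$movement_terms) base$cos_ta <- cos(strata$ta)
  for (a in spec$interaction_anthro) {
    av <- strata[[paste0(a, "_start")]]
    if ("log_sl" %in% spec$movement_terms) {
      base[[paste0("log_sl:", a, "_start")]] <- log(sl) * av
    }
    if ("cos_ta" %in% spec$movement_terms) {
      base[[paste0("cos_ta:", a, "_start")]] <- cos(strata$ta) * av
    }
  }
  X <- do.call(cbind, base)
  colnames(X) <- names(base)
  X
}

# precomputed stratum layout: rows must be ordered by stratum
clogit_groups <- function(stratum, case) {
  grp <- match(stratum, unique(stratum))
  sizes <- tabulate(grp)
  list(
    grp = grp, S = max(grp), sizes = sizes,
    uniform = length(unique(sizes)) == 1L, m = sizes[1],
    used = which(case == 1L)
  )
}

# conditional (matched-stratum) logistic log-likelihood, gradient and Hessian;
# uniform-stratum fast path reshapes eta to an m x S matrix
clogit_loglik <- function(beta, X, gs) {
  eta <- as.numeric(X %*% beta)
  if (gs$uniform) {
    E <- matrix(eta, nrow = gs$m)
    mxs <- E[1L, ]
    if (gs$m > 1L) for (r in 2:gs$m) mxs <- pmax(mxs, E[r, ])
    W <- exp(E - rep(mxs, each = gs$m))
    denom <- .colSums(W, gs$m, gs$S)
    p <- as.numeric(W / rep(denom, each = gs$m))
  } else {
    mxs <- vapply(split(eta, gs$grp), max, 0) # grp integer: numeric level order
    w <- exp(eta - mxs[gs$grp])
    denom <- as.numeric(rowsum(w, gs$grp))
    p <- w / denom[gs$grp]
  }
  ll <- sum(eta[gs$used]) - sum(log(denom)) - sum(mxs)
  g <- colSums(X[gs$used, , drop = FALSE]) - colSums(p * X)
  M <- rowsum(p * X, gs$grp) # per-stratum expected covariate
  H <- -(crossprod(sqrt(p) * X) - crossprod(M))
  list(ll = ll, grad = g, hess = H, p = p)
}

#' Conditional logistic regression on matched strata
#'
#' Maximizes the conditional log-likelihood
#' `sum_s [eta_used - log sum_j exp(eta_j)]` by Newton-Raphson on the
#' analytic gradient and Hessian (deterministic given the data; step-halving
#' safeguard; convergence when the gradient infinity-norm falls below `tol`).
#' Standard errors come from the inverse observed information. Columns with
#' no within-stratum contrast are dropped with a warning (no information);
#' runaway coefficients (complete separation) flag the fit non-converged and
#' its CI is reported as infinite.
#'
#' @param strata tibble with `stratum_id`, `case` and covariate columns.
#' @param spec an [issa_spec()].
#' @param tol gradient convergence tolerance (default 1e-8).
#' @param max_iter Newton iterations (default 50).
#' @param beta_max absolute coefficient bound beyond which separation is
#'   declared (default 15; covariates are standardized).
#' @param min_strata minimum complete strata required (default 30); fewer is
#'   an error, the per-individual exclusion rule.
#' @return object of class `issa_fit`: `beta`, `se`, `vcov`, `loglik`,
#'   `n_strata`, `converged`, `dropped` (aliased columns).
#' @export
fit_clogit <- function(strata, spec, tol = 1e-8, max_iter = 50,
                       beta_max = 15, min_strata = 30) {
  strata <- strata[order(strata$stratum_id, -strata$case), , drop = FALSE]
  X <- build_design(strata, spec)
  stratum <- strata$stratum_id
  case <- strata$case
  n_strata <- length(unique(stratum))
  if (n_strata < min_strata) {
    stop("only ", n_strata, " strata; minimum is ", min_strata)
  }
  # drop columns without within-stratum contrast, then rank-deficient ones
  grp <- match(stratum, unique(stratum))
  ctr <- X - rowsum(X, grp)[grp, , drop = FALSE] / tabulate(grp)[grp]
  novar <- apply(ctr, 2, function(v) max(abs(v)) < 1e-10)
  dropped <- colnames(X)[novar]
  X <- X[, !novar, drop = FALSE]
  if (ncol(X) == 0L) stop("no covariate has within-stratum contrast")
  qr_ <- qr(ctr[, !novar, drop = FALSE])
  if (qr_$rank < ncol(X)) {
    aliased <- colnames(X)[-qr_$pivot[seq_len(qr_$rank)]]
    warning("dropping rank-deficient column(s): ", paste(aliased, collapse = ", "))
    dropped <- c(dropped, aliased)
    X <- X[, qr_$pivot[seq_len(qr_$rank)], drop = FALSE]
  }
  if (length(dropped)) {
    warning("no within-stratum contrast, dropped: ", paste(dropped, collapse = ", "))
  }

  gs <- clogit_groups(stratum, case)
  beta <- rep(0, ncol(X))
  converged <- FALSE
  separated <- FALSE
  cur <- clogit_loglik(beta, X, gs)
  for (it in seq_len(max_iter)) {
    if (max(abs(cur$grad)) < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(
      solve(-cur$hess + diag(1e-10, ncol(X)), cur$grad),
      error = function(e) cur$grad / sqrt(sum(cur$grad^2))
    )
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      new <- clogit_loglik(cand, X, gs)
      if (is.finite(new$ll) && new$ll >= cur$ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    beta <- beta + lambda * step
    cur <- new
    if (max(abs(beta)) > beta_max) {
      separated <- TRUE
      break
    }
  }
  if (max(abs(cur$grad)) < tol) converged <- TRUE
  if (separated) converged <- FALSE
  vcov <- tryCatch(solve(-cur$hess), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(pmax(diag(vcov), 0))
  if (separated) se[] <- Inf
  names(beta) <- names(se) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(
    list(
      beta = beta, se = se, vcov = vcov, loglik = cur$ll,
      n_strata = n_strata, converged = converged, separated = separated,
      dropped = dropped, spec = spec
    ),
    class = "issa_fit"
  )
}

#' @export
print.issa_fit <- function(x, ...) {
  cat(sprintf(
    "<issa_fit> %d strata, loglik %.3f, %s\n", x$n_strata, x$loglik,
    if (x$converged) "converged" else "NOT converged"
  ))
  print(tibble::tibble(term = names(x$beta), beta = x$beta, se = x$se))
  invisible(x)
}

#' Update the tentative movement kernel from fitted movement coefficients
#'
#' Integrated step-selection adjustment: `shape' = shape + beta_log_sl`,
#' `1/scale' = 1/scale - beta_sl`, `kappa' = kappa + beta_cos_ta`. Updated
#' parameters outside the valid domain flag the update invalid.
#'
#' @param kernel tentative `movement_kernel`.
#' @param fit an `issa_fit` whose model included movement terms.
#' @return updated `movement_kernel` with attribute `valid`.
#' @export
update_kernel <- function(kernel, fit) {
  b <- fit$beta
  shape <- kernel$gamma_shape + if ("log_sl" %in% names(b)) b[["log_sl"]] else 0
  inv_scale <- 1 / kernel$gamma_scale - if ("sl" %in% names(b)) b[["sl"]] else 0
  kappa <- kernel$vm_kappa + if ("cos_ta" %in% names(b)) b[["cos_ta"]] else 0
  valid <- shape > 0 && inv_scale > 0 && kappa >= 0
  if (!valid) warning("updated kernel parameters leave the valid domain")
  out <- structure(
    list(
      gamma_shape = shape,
      gamma_scale = if (inv_scale > 0) 1 / inv_scale else NA_real_,
      vm_kappa = max(kappa, 0), vm_mu = 0, n_steps = kernel$n_steps
    ),
    class = "movement_kernel"
  )
  attr(out, "valid") <- valid
  out
}

#' Log relative selection strength between two habitat profiles
#'
#' `log-RSS = beta . (x1 - x2)` with a delta-method confidence interval from
#' the fit's covariance matrix.
#'
#' @param fit an `issa_fit`.
#' @param x1,x2 named numeric vectors covering the fit's habitat terms (on
#'   the same scale the model was fitted on).
#' @param level confidence level (default 0.95).
#' @return tibble with `log_rss, se, ci_low, ci_high`.
#' @export
log_rss <- function(fit, x1, x2, level = 0.95) {
  terms <- names(fit$beta)[names(fit$beta) %in% names(x1)]
  miss <- setdiff(names(x1), names(fit$beta))
  if (length(miss)) stop("terms absent from fit: ", paste(miss, collapse = ", "))
  d <- setNames(rep(0, length(fit$beta)), names(fit$beta))
  d[terms] <- as.numeric(x1[terms]) - as.numeric(x2[terms])
  est <- sum(fit$beta * d)
  se <- sqrt(as.numeric(t(d) %*% fit$vcov %*% d))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    log_rss = est, se = se,
    ci_low = est - z * se, ci_high = est + z * se
  )
}
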