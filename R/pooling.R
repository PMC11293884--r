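#' Tidy one iSSA fit into per-term rows
#'
#' @param fit an `issa_fit`.
#' @param animal_id,site,state identifiers carried into the row.
#' @return tibble with `site, state, animal_id, term, beta, se, n_strata,
#'   converged`.
#' @export
tidy_issa_fit <- function(fit, animal_id, site = "site", state = "all") {
  tibble::tibble(
    site = site, state = state, animal_id = animal_id,
    term = names(fit$beta), beta = unname(fit$beta), se = unname(fit$se),
    n_strata = fit$n_strata, converged = fit$converged
  )
}

#' Inverse-variance pooled coefficients per site x state x term
#'
#' Fixed-effect pooling: `beta_bar = sum(beta_i/se_i^2) / sum(1/se_i^2)`,
#' `se_bar = 1/sqrt(sum(1/se_i^2))`, 95% normal-theory confidence interval,
#' significance = CI excluding zero. Non-converged fits, infinite-SE terms
#' and terms present in fewer than two usable fits are excluded (reported
#' with `n_individuals` and, when nothing is usable, flagged not-estimable).
#' Cochran's Q and I^2 are reported for information only and never alter the
#' estimates.
#'
#' @param fits tidy per-term rows (from [tidy_issa_fit()], row-bound).
#' @param level confidence level, default 0.95.
#' @param min_fits minimum usable fits per term, default 2.
#' @return tibble with `site, state, term, beta_bar, se_bar, ci_low, ci_high,
#'   n_individuals, significant, estimable, q_het, i2`.
#' @export
pool_fits <- function(fits, level = 0.95, min_fits = 2) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  fits %>%
    dplyr::group_by(.data$site, .data$state, .data$term) %>%
    dplyr::group_modify(function(d, key) {
      ok <- d$converged & is.finite(d$beta) & is.finite(d$se) & d$se > 0
      d <- d[ok, , drop = FALSE]
      n <- nrow(d)
      if (n < min_fits) {
        return(tibble::tibble(
          beta_bar = NA_real_, se_bar = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_,
          n_individuals = n, significant = FALSE, estimable = FALSE,
          q_het = NA_real_, i2 = NA_real_
        ))
      }
      w <- 1 / d$se^2
      bb <- sum(w * d$beta) / sum(w)
      sb <- sqrt(1 / sum(w))
      q <- sum(w * (d$beta - bb)^2)
      i2 <- max(0, (q - (n - 1)) / q)
      tibble::tibble(
        beta_bar = bb, se_bar = sb,
        ci_low = bb - z * sb, ci_high = bb + z * sb,
        n_individuals = n,
        significant = (bb - z * sb) > 0 | (bb + z * sb) < 0,
        estimable = TRUE,
        q_het = q, i2 = ifelse(is.finite(i2), i2, NA_real_)
      )
    }) %>%
    dplyr::ungroup()
}

#' Compare pooled estimates between two sites
#'
#' One row per term x state with both sites' pooled estimates, per-site
#' significance flags (95% CI excluding zero) and a both-sites-significant
#' marker.
#'
#' @param pooled_a,pooled_b results of [pool_fits()] for the two sites.
#' @return tibble with suffixed columns `_a`, `_b` plus `both_significant`.
#' @export
compare_sites <- function(pooled_a, pooled_b) {
  keep <- c(
    "state", "term", "beta_bar", "se_bar", "ci_low", "ci_high",
    "n_individuals", "significant", "estimable"
  )
  a <- pooled_a[, c(keep)]
  b <- pooled_b[, c(keep)]
  out <- dplyr::full_join(a, b,
    by = c("state", "term"), suffix = c("_a", "_b")
  )
  out$both_significant <- isTRUE_v(out$significant_a) & isTRUE_v(out$significant_b)
  dplyr::arrange(out, .data$state, .data$term)
}

isTRUE_v <- function(x) !is.na(x) & x

#' Forest-plot style figure of pooled estimates by site
#'
#' Mirrors the usual two-site pooled-coefficient comparison: one row per
#' term, point = pooled beta, bar = 95% CI, solid where significant. Needs
#' ggplot2 (suggested).
#'
#' @param comparison result of [compare_sites()].
#' @param site_names length-2 labels.
#' @export
plot_pooled_comparison <- function(comparison, site_names = c("site A", "site B")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  long <- dplyr::bind_rows(
    tibble::tibble(
      state = comparison$state, term = comparison$term,
      site = site_names[1], beta = comparison$beta_bar_a,
      lo = comparison$ci_low_a, hi = comparison$ci_high_a,
      sig = isTRUE_v(comparison$significant_a)
    ),
    tibble::tibble(
      state = comparison$state, term = comparison$term,
      site = site_names[2], beta = comparison$beta_bar_b,
      lo = comparison$ci_low_b, hi = comparison$ci_high_b,
      sig = isTRUE_v(comparison$significant_b)
    )
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$beta, y = .data$term, color = .data$site,
      alpha = .data$sig)
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
      guide = "none") +
    ggplot2::facet_wrap(~state) +
    ggplot2::labs(x = "log relative selection strength", y = NULL)
}
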