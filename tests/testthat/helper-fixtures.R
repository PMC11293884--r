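# shared fixtures, built in code and cached for the test run

local_cache <- new.env(parent = emptyenv())

# small landscape + covariate stack (6 km, 60 m cells) for unit tests
test_stack <- function() {
  if (is.null(local_cache$stack)) {
    cfg <- landscape_config(
      extent_m = 6000, cell_m = 60,
      patch_density = c(
        forest = 1, shrub = 1, water = 0.4, hay_crop = 0.4,
        developed = 0.4, road4wd = 0.1
      ),
      seed = 99L
    )
    local_cache$stack <- build_covariates(generate_landscape(cfg))
  }
  local_cache$stack
}

# brute-force all-pairs nearest-target distance (m), the O(n^2) oracle
distance_to_brute <- function(mask, cell_m) {
  tgt <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      out[r, c] <- cell_m * sqrt(min((r - tgt[, 1])^2 + (c - tgt[, 2])^2))
    }
  }
  out
}

# direct per-cell 8-neighbor TRI oracle
tri_brute <- function(e) {
  nr <- nrow(e)
  nc <- ncol(e)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      s <- 0
      for (dr in -1:1) {
        for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          rr <- r + dr
          cc <- c + dc
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
            s <- s + (e[r, c] - e[rr, cc])^2
          }
        }
      }
      out[r, c] <- sqrt(s)
    }
  }
  out
}

# regular 4-h fix track moving `step_m` east per fix
make_regular_track <- function(n, step_m = 1000, interval_min = 240,
                               t0 = as.POSIXct("2023-01-01", tz = "UTC")) {
  tibble::tibble(
    animal_id = "T1",
    t = t0 + (seq_len(n) - 1L) * interval_min * 60,
    x = (seq_len(n) - 1L) * step_m,
    y = 0
  )
}

# toy strata for clogit tests: S strata x (1 used + n_avail) rows, covariates
# N(0,1), used chosen with probability proportional to exp(X beta)
make_toy_strata <- function(S, n_avail, beta, seed = 1) {
  set.seed(seed)
  k <- length(beta)
  m <- n_avail + 1L
  rows <- S * m
  X <- matrix(rnorm(rows * k), rows, k)
  colnames(X) <- names(beta)
  stratum <- rep(seq_len(S), each = m)
  case <- integer(rows)
  for (s in seq_len(S)) {
    idx <- which(stratum == s)
    eta <- X[idx, , drop = FALSE] %*% beta
    case[idx[sample.int(m, 1L, prob = exp(eta - max(eta)))]] <- 1L
  }
  out <- tibble::as_tibble(as.data.frame(X))
  out$stratum_id <- stratum
  out$case <- case
  out$sl <- 1
  out$ta <- 0
  out
}

wrap_angle_test <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

make_fit_rows <- function(betas, ses, site = "A", state = "all",
                          term = "x", converged = TRUE) {
  tibble::tibble(
    site = site, state = state,
    animal_id = paste0("A", seq_along(betas)),
    term = term, beta = betas, se = ses,
    n_strata = 100L, converged = converged
  )
}
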