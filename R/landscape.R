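# run code under a temporary RNG state seeded with `seed`; NULL = use current
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Land-cover classes and their integer raster codes
#' @export
landcover_codes <- function() {
  c(
    forest = 1L, shrub = 2L, water = 3L, hay_crop = 4L,
    developed = 5L, road4wd = 6L
  )
}

#' Synthetic landscape configuration
#'
#' @param extent_m side of the square domain (m); must be a multiple of `cell_m`.
#' @param cell_m cell size (m), default 30 (the common analysis grid).
#' @param patch_density expected patches per km^2, named for each land-cover
#'   class (`road4wd` entries count straight road transects instead of discs).
#' @param elevation_relief_m peak-to-trough amplitude of the smooth elevation
#'   field (m).
#' @param patch_radius_m typical disc-patch radius (m); log-normal spread.
#' @param seed integer RNG seed.
#' @export
landscape_config <- function(extent_m = 12000, cell_m = 30,
                             patch_density = c(
                               forest = 1.0, shrub = 1.0, water = 0.3,
                               hay_crop = 0.3, developed = 0.3, road4wd = 0.05
                             ),
                             elevation_relief_m = 600,
                             patch_radius_m = 4 * cell_m,
                             seed = 1L) {
  stopifnot(cell_m > 0, extent_m %% cell_m == 0, all(patch_density >= 0))
  dens <- c(
    forest = 0, shrub = 0, water = 0, hay_crop = 0,
    developed = 0, road4wd = 0
  )
  dens[names(patch_density)] <- patch_density
  structure(
    list(
      extent_m = extent_m, cell_m = cell_m, patch_density = dens,
      elevation_relief_m = elevation_relief_m,
      patch_radius_m = patch_radius_m, seed = seed
    ),
    class = "landscape_config"
  )
}

# paint disc patches of one class onto the code matrix (by reference semantics:
# returns the updated matrix); cells whose centers fall within radius
paint_disc <- function(m, cx, cy, radius, cell, code) {
  nr <- nrow(m)
  nc <- ncol(m)
  c0 <- max(1L, floor((cx - radius) / cell) + 1L)
  c1 <- min(nc, floor((cx + radius) / cell) + 1L)
  r0 <- max(1L, floor((cy - radius) / cell) + 1L)
  r1 <- min(nr, floor((cy + radius) / cell) + 1L)
  if (c0 > c1 || r0 > r1) return(m)
  xs <- ((c0:c1) - 0.5) * cell
  ys <- ((r0:r1) - 0.5) * cell
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  hit <- d2 <= max(radius, cell / 2)^2 # a patch always owns its center cell
  sub <- m[r0:r1, c0:c1, drop = FALSE]
  sub[hit] <- code
  m[r0:r1, c0:c1] <- sub
  m
}

paint_transect <- function(m, x0, y0, x1, y1, cell, code) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  n <- max(2L, ceiling(len / (cell / 2)))
  xs <- seq(x0, x1, length.out = n)
  ys <- seq(y0, y1, length.out = n)
  col <- pmin(pmax(floor(xs / cell) + 1L, 1L), ncol(m))
  row <- pmin(pmax(floor(ys / cell) + 1L, 1L), nrow(m))
  m[cbind(row, col)] <- code
  m
}

#' Generate a synthetic landscape
#'
#' Land-cover patches are Poisson-placed discs rasterized onto the grid
#' (classes painted in code order, later classes overprint); 4WD roads are
#' random straight 1-cell-wide transects so distance-to-road gradients exist;
#' elevation is a sum of low-frequency sinusoids rescaled to the configured
#' relief. Deterministic for a fixed seed. Classes with positive density are
#' guaranteed at least one patch (a Poisson draw of zero is promoted to one).
#'
#' @param cfg a [landscape_config()].
#' @return list with `class` (a `cov_grid` of integer codes, 0 = background),
#'   `elevation` (a `cov_grid`), `classes` (name -> code map), `n_patches`
#'   (realized patch/transect count per class) and `cfg`.
#' @export
generate_landscape <- function(cfg) {
  n <- as.integer(cfg$extent_m / cfg$cell_m)
  if (n < 3L) stop("degenerate extent: fewer than 3 x 3 cells")
  codes <- landcover_codes()
  area_km2 <- (cfg$extent_m / 1000)^2
  with_seed(cfg$seed, {
    cls <- matrix(0L, n, n)
    n_patches <- setNames(integer(length(codes)), names(codes))
    for (nm in setdiff(names(codes), "road4wd")) {
      dens <- cfg$patch_density[[nm]]
      if (dens <= 0) next
      k <- stats::rpois(1L, dens * area_km2)
      if (k == 0L) k <- 1L
      n_patches[[nm]] <- k
      cx <- stats::runif(k, 0, cfg$extent_m)
      cy <- stats::runif(k, 0, cfg$extent_m)
      rad <- stats::rlnorm(k, log(cfg$patch_radius_m), 0.35)
      for (i in seq_len(k)) {
        cls <- paint_disc(cls, cx[i], cy[i], rad[i], cfg$cell_m, codes[[nm]])
      }
    }
    if (cfg$patch_density[["road4wd"]] > 0) {
      k <- stats::rpois(1L, cfg$patch_density[["road4wd"]] * area_km2)
      if (k == 0L) k <- 1L
      n_patches[["road4wd"]] <- k
      for (i in seq_len(k)) {
        # random chord: a point inside the domain plus a random direction,
        # extended to the boundary both ways
        px <- stats::runif(1, 0, cfg$extent_m)
        py <- stats::runif(1, 0, cfg$extent_m)
        th <- stats::runif(1, 0, pi)
        L <- 2 * cfg$extent_m
        cls <- paint_transect(
          cls,
          px - L * cos(th), py - L * sin(th),
          px + L * cos(th), py + L * sin(th),
          cfg$cell_m, codes[["road4wd"]]
        )
      }
    }
    # elevation: a handful of low-frequency plane waves, rescaled to relief
    ctr <- grid_centers(cov_grid(cls, cfg$cell_m))
    e <- matrix(0, n, n)
    for (k in 1:5) {
      wav <- cfg$extent_m / stats::runif(1, 1, 3)
      th <- stats::runif(1, 0, 2 * pi)
      ph <- stats::runif(1, 0, 2 * pi)
      phase <- outer(ctr$y * sin(th), ctr$x * cos(th), "+")
      e <- e + sin(2 * pi * phase / wav + ph) / k
    }
    rng <- range(e)
    if (diff(rng) > 0) {
      e <- (e - rng[1]) / diff(rng) * cfg$elevation_relief_m
    }
    list(
      class = cov_grid(cls, cfg$cell_m),
      elevation = cov_grid(e, cfg$cell_m),
      classes = codes,
      n_patches = n_patches,
      cfg = cfg
    )
  })
}
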