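#' @importFrom stats cor quantile sd setNames
NULL

# ---- exact Euclidean distance transform ------------------------------------

# 1-D squared-distance lower envelope (Felzenszwalb & Huttenlocher).
# f: squared distances sampled on an integer lattice; returns, per position q,
# min_p (q - p)^2 + f[p]. Exact in floating point for the magnitudes used here.
dt1d <- function(f) {
  n <- length(f)
  INF <- 1e18
  f <- pmin(f, INF)
  v <- integer(n)
  z <- numeric(n + 1L)
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  k <- 1L
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  out <- numeric(n)
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    out[q] <- (q - v[k])^2 + f[v[k]]
  }
  out
}

# squared distance (in cell units) from every cell to the nearest TRUE cell
edt_squared <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  d <- matrix(Inf, nr, nc)
  d[mask] <- 0
  if (nr > 1L) {
    for (r in 2:nr) d[r, ] <- pmin(d[r, ], d[r - 1L, ] + 1)
    for (r in (nr - 1L):1L) d[r, ] <- pmin(d[r, ], d[r + 1L, ] + 1)
  }
  g <- d * d
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) out[r, ] <- dt1d(g[r, ])
  out
}

#' Distance-to-class raster
#'
#' Euclidean distance in meters, measured cell-center to cell-center, from
#' every cell to the nearest cell whose code is in `class_codes`; zero on
#' target cells. If the landscape holds no cell of the class, the layer is
#' filled with the extent diagonal as a sentinel and flagged degenerate
#' (attribute `degenerate`); downstream model assembly drops flagged layers.
#'
#' @param class_grid a `cov_grid` of integer land-cover codes.
#' @param class_codes integer codes counting as the target class.
#' @return a `cov_grid` of distances (m), possibly with `attr(, "degenerate")`.
#' @export
distance_to <- function(class_grid, class_codes) {
  mask <- matrix(class_grid$values %in% class_codes,
    nrow = nrow(class_grid$values)
  )
  out <- class_grid
  if (!any(mask)) {
    ext <- grid_extent(class_grid)
    sentinel <- sqrt((ext["xmax"] - ext["xmin"])^2 + (ext["ymax"] - ext["ymin"])^2)
    out$values <- matrix(as.numeric(sentinel),
      nrow = nrow(mask), ncol = ncol(mask)
    )
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out$values <- sqrt(edt_squared(mask)) * class_grid$cell_m
  attr(out, "degenerate") <- FALSE
  out
}

#' Log-transform a distance layer
#'
#' `ln(d + offset)` with a half-cell offset (15 m on a 30 m grid) so the
#' transform is defined on-feature (d = 0) and scale-aware; monotone in d.
#'
#' @param g a `cov_grid` of non-negative distances (m).
#' @param offset_m additive offset before the log; default half a cell width.
#' @export
log_distance <- function(g, offset_m = g$cell_m / 2) {
  if (any(g$values < 0, na.rm = TRUE)) stop("negative distances in layer")
  out <- g
  out$values <- log(g$values + offset_m)
  out
}

#' Terrain Ruggedness Index (Riley)
#'
#' Per cell, the square root of the summed squared elevation differences with
#' the 8 neighboring cells; edge cells use the neighbors that exist.
#' Translation-invariant: adding a constant to elevation leaves TRI unchanged.
#'
#' @param elev a `cov_grid` of elevations (m).
#' @export
terrain_ruggedness <- function(elev) {
  e <- elev$values
  nr <- nrow(e)
  nc <- ncol(e)
  acc <- matrix(0, nr, nc)
  pad <- matrix(NA_real_, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- e
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
      diff2 <- (e - nb)^2
      diff2[is.na(diff2)] <- 0
      acc <- acc + diff2
    }
  }
  out <- elev
  out$values <- sqrt(acc)
  out
}

# ---- covariate stack --------------------------------------------------------

#' Build the covariate stack from a synthetic (or ingested) landscape
#'
#' Derives, on the landscape's grid: one log-distance layer per land-cover
#' class (`dist_<class>_log`), `elevation`, and `tri`; records which layers
#' are log-transformed, which are degenerate (class absent), which are
#' anthropogenic, and per-layer mean/SD over all cells used for z-scoring.
#'
#' @param landscape result of [generate_landscape()], or a list with elements
#'   `class` (a `cov_grid` of integer codes), `elevation` (a `cov_grid`) and
#'   `classes` (named integer vector mapping class name to code).
#' @param log_offset_m offset for [log_distance()]; default half a cell.
#' @return an object of class `cov_stack`.
#' @export
build_covariates <- function(landscape, log_offset_m = landscape$class$cell_m / 2) {
  cls <- landscape$classes
  layers <- list()
  flagged <- character(0)
  for (nm in names(cls)) {
    d <- distance_to(landscape$class, cls[[nm]])
    lname <- paste0("dist_", nm, "_log")
    if (isTRUE(attr(d, "degenerate"))) flagged <- c(flagged, lname)
    layers[[lname]] <- log_distance(d, offset_m = log_offset_m)$values
  }
  layers$elevation <- landscape$elevation$values
  layers$tri <- terrain_ruggedness(landscape$elevation)$values
  center <- vapply(layers, function(m) mean(m, na.rm = TRUE), 0)
  scale <- vapply(layers, function(m) sd(as.vector(m), na.rm = TRUE), 0)
  scale[!is.finite(scale) | scale == 0] <- 1
  g <- landscape$class
  structure(
    list(
      layers = layers,
      cell_m = g$cell_m, xmin = g$xmin, ymin = g$ymin,
      nrow = nrow(g$values), ncol = ncol(g$values),
      log_layers = paste0("dist_", names(cls), "_log"),
      anthro_layers = intersect(
        c("dist_developed_log", "dist_hay_crop_log", "dist_road4wd_log"),
        names(layers)
      ),
      flagged = flagged,
      center = center, scale = scale
    ),
    class = "cov_stack"
  )
}

#' @export
print.cov_stack <- function(x, ...) {
  cat(sprintf(
    "<cov_stack> %d layers on %d x %d grid (%g m cells)\n",
    length(x$layers), x$nrow, x$ncol, x$cell_m
  ))
  cat(" layers:", paste(names(x$layers), collapse = ", "), "\n")
  if (length(x$flagged)) cat(" degenerate:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

stack_grid <- function(stack, layer) {
  cov_grid(stack$layers[[layer]],
    cell_m = stack$cell_m, xmin = stack$xmin, ymin = stack$ymin
  )
}

#' Names of layers usable in a selection model (degenerate layers excluded)
#' @param stack a `cov_stack`.
#' @export
usable_layers <- function(stack) setdiff(names(stack$layers), stack$flagged)

#' Extract covariate values at points
#'
#' Nearest-cell extraction (no interpolation — distance layers are piecewise
#' and interpolation would blur the on-feature zero). Points outside the
#' extent yield `NA`; strata containing such points are dropped later.
#'
#' @param stack a `cov_stack`.
#' @param x,y point coordinates (m).
#' @param layers layer names; default all usable layers.
#' @param standardized if `TRUE`, values are z-scored with the stack's stored
#'   per-layer mean/SD.
#' @param wrap treat the landscape as periodic (toroidal): coordinates are
#'   wrapped modulo the extent instead of going missing. Used by the
#'   estimator-validation experiments, where a boundaryless landscape keeps
#'   the generative model exactly inside the fitted model class.
#' @return a tibble with one column per layer.
#' @export
extract_at <- function(stack, x, y, layers = usable_layers(stack),
                       standardized = TRUE, wrap = FALSE) {
  stopifnot(length(x) == length(y))
  col <- floor((x - stack$xmin) / stack$cell_m) + 1L
  row <- floor((y - stack$ymin) / stack$cell_m) + 1L
  if (wrap) {
    col <- ((col - 1L) %% stack$ncol) + 1L
    row <- ((row - 1L) %% stack$nrow) + 1L
  }
  ok <- !is.na(col) & !is.na(row) & col >= 1L & col <= stack$ncol &
    row >= 1L & row <= stack$nrow
  idx <- (col - 1L) * stack$nrow + row
  out <- lapply(layers, function(nm) {
    v <- rep(NA_real_, length(x))
    v[ok] <- stack$layers[[nm]][idx[ok]]
    if (standardized) v <- (v - stack$center[[nm]]) / stack$scale[[nm]]
    v
  })
  names(out) <- layers
  tibble::as_tibble(out)
}

#' Screen collinear covariate layers
#'
#' Pearson correlations among layers at sampled points; while any pair has
#' `|r| > r_max`, the member of the worst pair with the larger mean absolute
#' correlation against the remaining layers is dropped (ties alphabetical).
#' Constant layers are dropped first with a warning (correlation undefined).
#'
#' @param stack a `cov_stack`.
#' @param sample_xy data frame / tibble with `x`, `y` of sampling points
#'   (>= 30 required).
#' @param r_max correlation threshold; default 0.60.
#' @param layers candidate layer names; default all usable layers.
#' @return character vector of retained layer names (alphabetical).
#' @export
screen_collinear <- function(stack, sample_xy, r_max = 0.60,
                             layers = usable_layers(stack)) {
  stopifnot(nrow(sample_xy) >= 30, length(layers) >= 2)
  vals <- extract_at(stack, sample_xy$x, sample_xy$y,
    layers = layers, standardized = FALSE
  )
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  sds <- vapply(vals, sd, 0)
  if (any(sds == 0)) {
    warning(
      "dropping constant layer(s): ",
      paste(names(vals)[sds == 0], collapse = ", ")
    )
    vals <- vals[, sds > 0, drop = FALSE]
  }
  keep <- sort(names(vals))
  repeat {
    if (length(keep) < 2L) break
    cm <- abs(cor(vals[, keep, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= r_max) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    pair <- sort(keep[worst])
    mean_abs <- vapply(pair, function(nm) mean(cm[nm, setdiff(keep, nm)]), 0)
    # drop the member more correlated with everything else; ties alphabetical
    drop_nm <- pair[which.max(mean_abs)]
    if (mean_abs[1] == mean_abs[2]) drop_nm <- pair[1L]
    keep <- setdiff(keep, drop_nm)
  }
  keep
}
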