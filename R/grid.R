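#' Grid raster container
#'
#' A `cov_grid` is a minimal single-band raster on a regular planar lattice:
#' a numeric matrix whose rows index y (south to north) and columns index x
#' (west to east), plus the cell size and the coordinates of the lower-left
#' corner. All layers of a study share one grid, one planar CRS in meters.
#'
#' @param values numeric matrix, rows = y, cols = x.
#' @param cell_m cell size in meters.
#' @param xmin,ymin coordinates of the lower-left corner of the grid (meters).
#' @return an object of class `cov_grid`.
#' @export
cov_grid <- function(values, cell_m, xmin = 0, ymin = 0) {
  stopifnot(is.matrix(values), is.numeric(cell_m), cell_m > 0)
  structure(
    list(values = values, cell_m = cell_m, xmin = xmin, ymin = ymin),
    class = "cov_grid"
  )
}

#' @export
print.cov_grid <- function(x, ...) {
  cat(sprintf(
    "<cov_grid> %d x %d cells, %g m cells, origin (%g, %g)\n",
    nrow(x$values), ncol(x$values), x$cell_m, x$xmin, x$ymin
  ))
  invisible(x)
}

#' @export
dim.cov_grid <- function(x) dim(x$values)

grid_extent <- function(g) {
  c(
    xmin = g$xmin, xmax = g$xmin + ncol(g$values) * g$cell_m,
    ymin = g$ymin, ymax = g$ymin + nrow(g$values) * g$cell_m
  )
}

#' Coordinates of cell centers
#'
#' @param g a `cov_grid`.
#' @return list with `x` (length ncol) and `y` (length nrow) center coordinates.
#' @export
grid_centers <- function(g) {
  list(
    x = g$xmin + (seq_len(ncol(g$values)) - 0.5) * g$cell_m,
    y = g$ymin + (seq_len(nrow(g$values)) - 0.5) * g$cell_m
  )
}

# row/col of the cell containing (x, y); NA outside the extent
grid_rowcol <- function(g, x, y) {
  col <- floor((x - g$xmin) / g$cell_m) + 1L
  row <- floor((y - g$ymin) / g$cell_m) + 1L
  bad <- col < 1L | col > ncol(g$values) | row < 1L | row > nrow(g$values) |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = row, col = col)
}

#' Look up grid values at point coordinates (nearest cell, no interpolation)
#'
#' @param g a `cov_grid`.
#' @param x,y point coordinates in meters.
#' @return numeric vector; `NA` for points outside the extent.
#' @export
grid_lookup <- function(g, x, y) {
  rc <- grid_rowcol(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- g$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Write a grid as an ESRI ASCII raster (plain text)
#'
#' @param g a `cov_grid`.
#' @param path output file.
#' @param nodata value used for `NA` cells.
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  v <- g$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$cell_m),
    sprintf("NODATA_value %g", nodata)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  # ASCII grids are stored top row first (north at the top)
  for (r in rev(seq_len(nrow(v)))) {
    writeLines(paste(format(v[r, ], trim = TRUE, digits = 10), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file written by [write_ascii_grid()] or any GIS ASCII export.
#' @return a `cov_grid`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  vals <- scan(text = body, quiet = TRUE)
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE] # back to south-up row order
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  cov_grid(m, cell_m = hdr$cellsize, xmin = hdr$xllcorner, ymin = hdr$yllcorner)
}
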