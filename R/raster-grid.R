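#' Gridded raster container
#'
#' A minimal in-memory raster: a numeric matrix on a regular projected grid
#' with cell-center registration. Row 1 is the northernmost row; `NA` cells
#' are nodata and are ignored by all arithmetic. Coordinates are meters in a
#' projected CRS; areas derived from the transform are reported in km^2.
#'
#' @param values numeric matrix (row 1 = north). `NA` marks nodata.
#' @param cellsize cell edge length in meters (> 0).
#' @param xmin x coordinate of the west edge (left edge of column 1), meters.
#' @param ymax y coordinate of the north edge (top edge of row 1), meters.
#' @param crs text identifier of the projected CRS (free-form, e.g.
#'   "EPSG:32646" or "local-metric").
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, cellsize = 1000, xmin = 0, ymax = NULL,
                        crs = "local-metric") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cellsize), length(cellsize) == 1L, cellsize > 0)
  if (is.null(ymax)) ymax <- nrow(values) * cellsize
  structure(
    list(values = values, cellsize = as.numeric(cellsize),
         xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         crs = as.character(crs)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, %.0f m, crs=%s\n",
              nrow(v), ncol(v), x$cellsize, x$crs))
  ok <- !is.na(v)
  if (any(ok))
    cat(sprintf("  valid: %d cells, range [%.6g, %.6g]\n",
                sum(ok), min(v[ok]), max(v[ok])))
  else cat("  all nodata\n")
  invisible(x)
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Cell-center coordinates
#'
#' @param grid a `raster_grid`.
#' @return list with vectors `x` (by column) and `y` (by row), meters.
#' @export
cell_centers <- function(grid) {
  stopifnot(is_raster_grid(grid))
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cellsize
  list(x = grid$xmin + (seq_len(nc) - 0.5) * cs,
       y = grid$ymax - (seq_len(nr) - 0.5) * cs)
}

#' Area of one grid cell in km^2
#' @param grid a `raster_grid`.
#' @export
cell_area_km2 <- function(grid) {
  stopifnot(is_raster_grid(grid))
  (grid$cellsize / 1000)^2
}

# TRUE when two grids share shape, transform and CRS (tolerance in meters).
same_grid <- function(a, b, tol = 1e-6) {
  is_raster_grid(a) && is_raster_grid(b) &&
    all(dim(a$values) == dim(b$values)) &&
    abs(a$cellsize - b$cellsize) < tol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    identical(a$crs, b$crs)
}

stop_if_grid_mismatch <- function(a, b, what = "grids") {
  if (!same_grid(a, b))
    stop(what, " are not on the same grid (shape/transform/CRS mismatch)",
         call. = FALSE)
  invisible(TRUE)
}

#' Resample a raster onto a template grid
#'
#' Nearest-neighbour or bilinear resampling by cell-center lookup. Cells whose
#' center falls outside the source extent, or whose source support is nodata,
#' become nodata.
#'
#' @param grid source `raster_grid`.
#' @param template target `raster_grid` (values ignored; geometry used).
#' @param method `"nearest"` (categorical-safe) or `"bilinear"`.
#' @return a `raster_grid` on the template geometry.
#' @export
resample_grid <- function(grid, template, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  stopifnot(is_raster_grid(grid), is_raster_grid(template))
  src <- grid$values
  nr_s <- nrow(src); nc_s <- ncol(src)
  tc <- cell_centers(template)
  # fractional source indices of each target cell center
  fi <- (grid$ymax - rep(tc$y, times = length(tc$x))) / grid$cellsize + 0.5
  fj <- (rep(tc$x, each = length(tc$y)) - grid$xmin) / grid$cellsize + 0.5
  out <- rep(NA_real_, length(fi))
  if (method == "nearest") {
    i <- round(fi); j <- round(fj)
    ok <- i >= 1 & i <= nr_s & j >= 1 & j <= nc_s
    out[ok] <- src[cbind(i[ok], j[ok])]
  } else {
    i0 <- floor(fi); j0 <- floor(fj)
    wi <- fi - i0; wj <- fj - j0
    i0c <- pmin(pmax(i0, 1L), nr_s); i1c <- pmin(pmax(i0 + 1, 1L), nr_s)
    j0c <- pmin(pmax(j0, 1L), nc_s); j1c <- pmin(pmax(j0 + 1, 1L), nc_s)
    ok <- fi >= 0.5 & fi <= nr_s + 0.5 & fj >= 0.5 & fj <= nc_s + 0.5
    v00 <- src[cbind(i0c, j0c)]; v01 <- src[cbind(i0c, j1c)]
    v10 <- src[cbind(i1c, j0c)]; v11 <- src[cbind(i1c, j1c)]
    out <- (1 - wi) * ((1 - wj) * v00 + wj * v01) +
      wi * ((1 - wj) * v10 + wj * v11)
    out[!ok] <- NA_real_
  }
  if (all(is.na(out)))
    stop("resampled layer does not overlap the template extent", call. = FALSE)
  m <- matrix(out, nrow = nrow(template$values), ncol = ncol(template$values))
  raster_grid(m, template$cellsize, template$xmin, template$ymax, template$crs)
}
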