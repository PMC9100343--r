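# summed-area table; m is 0/1 (or numeric) with no NAs
sat <- function(m) {
  s <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed
  t(s)
}

# sum of m over the (2r+1)^2 window centered at each cell, edges truncated
box_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- sat(m)
  i <- seq_len(nr); j <- seq_len(nc)
  i0 <- pmax(i - r, 1L); i1 <- pmin(i + r, nr)
  j0 <- pmax(j - r, 1L); j1 <- pmin(j + r, nc)
  S[cbind(rep(i1 + 1L, nc), rep(j1 + 1L, each = nr))] -
    S[cbind(rep(i0, nc),      rep(j1 + 1L, each = nr))] -
    S[cbind(rep(i1 + 1L, nc), rep(j0, each = nr))] +
    S[cbind(rep(i0, nc),      rep(j0, each = nr))]
}

#' Shannon landscape-diversity map
#'
#' Moving-window Shannon diversity of land-cover composition:
#' SHDI = -sum_k p_k ln p_k, where p_k is the proportion of class k among the
#' valid cells of the square window (edge-truncated) centered on each cell.
#' A monomorphic window scores 0; a window with no valid cells is nodata.
#'
#' @param lc a [land_cover_grid()].
#' @param window_radius_cells window half-width in cells (window edge is
#'   `2r + 1`); default 5.
#' @return a [raster_grid()] of diversity values, nodata-masked like the
#'   input.
#' @export
shdi_map <- function(lc, window_radius_cells = 5) {
  stopifnot(inherits(lc, "land_cover_grid"), window_radius_cells >= 1)
  r <- as.integer(window_radius_cells)
  v <- lc$grid$values
  classes <- sort(unique(v[!is.na(v)]))
  nr <- nrow(v); nc <- ncol(v)
  valid <- !is.na(v)
  nvalid <- box_sum(valid + 0, r)
  H <- matrix(0, nr, nc)
  for (k in classes) {
    cnt <- box_sum((valid & v == k) + 0, r)
    p <- ifelse(nvalid > 0, cnt / nvalid, 0)
    H <- H - ifelse(p > 0, p * log(p), 0)
  }
  H[nvalid == 0] <- NA_real_
  H[!valid] <- NA_real_  # diversity reported only where land cover is defined
  raster_grid(H, lc$grid$cellsize, lc$grid$xmin, lc$grid$ymax, lc$grid$crs)
}

# squared distance from points (px,py) to segment (x1,y1)-(x2,y2), vectorized
# over the points
seg_dist2 <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return((px - x1)^2 + (py - y1)^2)
  t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / L2, 0), 1)
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

#' Euclidean distance-to-feature layer
#'
#' Exact straight-line distance, in meters, from every cell center to the
#' nearest feature geometry (points, polyline segments, polygon boundaries;
#' cell centers inside a polygon score 0). Computed on the projected grid,
#' not by raster chamfer propagation.
#'
#' @param features a [feature_set()].
#' @param template [raster_grid()] supplying geometry and nodata mask.
#' @return a [raster_grid()] of distances (m), masked like the template.
#' @export
distance_layer <- function(features, template) {
  stopifnot(inherits(features, "feature_set"), is_raster_grid(template))
  cc <- cell_centers(template)
  nr <- nrow(template$values); nc <- ncol(template$values)
  px <- rep(cc$x, each = nr)
  py <- rep(cc$y, times = nc)
  d2 <- rep(Inf, nr * nc)
  pts <- features$points
  if (!is.null(pts))
    for (k in seq_len(nrow(pts)))
      d2 <- pmin(d2, (px - pts[k, 1])^2 + (py - pts[k, 2])^2)
  segs_of <- function(ring, closed) {
    m <- nrow(ring)
    idx <- if (closed) cbind(seq_len(m), c(seq_len(m)[-1], 1L))
           else cbind(seq_len(m - 1L), seq_len(m)[-1])
    idx
  }
  for (l in features$lines) {
    idx <- segs_of(l, closed = FALSE)
    for (k in seq_len(nrow(idx)))
      d2 <- pmin(d2, seg_dist2(px, py, l[idx[k, 1], 1], l[idx[k, 1], 2],
                               l[idx[k, 2], 1], l[idx[k, 2], 2]))
  }
  for (p in features$polygons) {
    ring <- p
    m <- nrow(ring)
    if (ring[1, 1] == ring[m, 1] && ring[1, 2] == ring[m, 2])
      ring <- ring[-m, , drop = FALSE]
    idx <- segs_of(ring, closed = TRUE)
    for (k in seq_len(nrow(idx)))
      d2 <- pmin(d2, seg_dist2(px, py, ring[idx[k, 1], 1], ring[idx[k, 1], 2],
                               ring[idx[k, 2], 1], ring[idx[k, 2], 2]))
  }
  if (length(features$polygons)) {
    inside <- polygon_mask(features$polygons, template)
    d2[as.vector(inside)] <- 0
  }
  out <- matrix(sqrt(d2), nr, nc)
  out[is.na(template$values)] <- NA_real_
  raster_grid(out, template$cellsize, template$xmin, template$ymax,
              template$crs)
}
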