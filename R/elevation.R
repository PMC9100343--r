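#' Random point sample of (elevation, potential) pairs
#'
#' Uniform sampling without replacement over cells valid in both the
#' potential surface and the DEM; reproducible by seed (the global RNG state
#' is left untouched).
#'
#' @param pm a `potential_map`.
#' @param dem [raster_grid()] of elevations (m), aligned to `pm`.
#' @param n number of points.
#' @param seed RNG seed.
#' @return data.frame with columns `elevation_m`, `inrpi`; attributes `seed`
#'   and `epoch`.
#' @export
sample_points <- function(pm, dem, n, seed = 1L) {
  stopifnot(inherits(pm, "potential_map"), is_raster_grid(dem))
  stop_if_grid_mismatch(pm$grid, dem, "potential map and DEM")
  ok <- which(!is.na(pm$grid$values) & !is.na(dem$values))
  if (n > length(ok))
    stop("requested ", n, " points but only ", length(ok),
         " valid cells are available", call. = FALSE)
  idx <- withr::with_seed(seed, sample(ok, n))
  out <- data.frame(elevation_m = dem$values[idx],
                    inrpi = pm$grid$values[idx])
  attr(out, "seed") <- seed
  attr(out, "epoch") <- pm$epoch
  out
}

# OLS through a fixed design; returns coef and SSE
ols_sse <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  list(coef = fit$coefficients, sse = sum(fit$residuals^2))
}

#' Two-segment (breakpoint) regression of potential on elevation
#'
#' Fits the continuous piecewise-linear model
#' y = b0 + b1 * x + b2 * max(x - c, 0) (x in km) by exhaustive search over
#' candidate breakpoints c, ordinary least squares at each candidate, keeping
#' the minimum-SSE fit. Slopes are reported per 1000 m of elevation. The
#' unconstrained OLS slope over the points above the breakpoint is reported
#' alongside, and the fit is flagged as having no material breakpoint when
#' the two-segment model improves the single-line SSE by less than 1%.
#'
#' @param pairs data.frame with `elevation_m` and `inrpi` (e.g. from
#'   [sample_points()]).
#' @param step candidate grid step in meters; `NULL` (default) searches every
#'   interior sampled elevation.
#' @param min_points minimum points required on each side of a candidate.
#' @return a `breakpoint_fit`: `breakpoint_m`, `slope_pre`, `slope_post`,
#'   `slope_post_unconstrained` (all per 1000 m), `intercept`, `sse`,
#'   `sse_line`, `n`, `material`.
#' @export
fit_breakpoint <- function(pairs, step = NULL, min_points = 3L) {
  stopifnot(all(c("elevation_m", "inrpi") %in% names(pairs)))
  e <- pairs$elevation_m; y <- pairs$inrpi
  keep <- !is.na(e) & !is.na(y)
  e <- e[keep]; y <- y[keep]
  n <- length(e)
  if (n < 20) stop("need at least 20 points to fit a breakpoint",
                   call. = FALSE)
  if (diff(range(e)) <= 0)
    stop("all elevations are equal; breakpoint undefined", call. = FALSE)
  x <- e / 1000  # slopes per km
  es <- sort(unique(e))
  cand <- if (is.null(step)) es[-c(1L, length(es))]
          else seq(min(e), max(e), by = step)
  # keep candidates with enough support on each side
  ecdf_lo <- vapply(cand, function(c) sum(e < c), 0L)
  cand <- cand[ecdf_lo >= min_points & (n - ecdf_lo) >= min_points]
  if (!length(cand))
    stop("elevation spread too degenerate for a breakpoint search",
         call. = FALSE)
  one <- ols_sse(cbind(1, x), y)
  best <- NULL
  for (c_m in cand) {
    hinge <- pmax(x - c_m / 1000, 0)
    f <- ols_sse(cbind(1, x, hinge), y)
    if (is.null(best) || f$sse < best$sse)
      best <- list(sse = f$sse, coef = f$coef, c_m = c_m)
  }
  b <- best$coef
  post_pts <- e > best$c_m
  slope_post_unc <- if (sum(post_pts) >= 2 && diff(range(x[post_pts])) > 0)
    ols_sse(cbind(1, x[post_pts]), y[post_pts])$coef[2] else NA_real_
  improvement <- (one$sse - best$sse) / one$sse
  structure(list(
    breakpoint_m = best$c_m,
    slope_pre = unname(b[2]),
    slope_post = unname(b[2] + b[3]),
    slope_post_unconstrained = unname(slope_post_unc),
    intercept = unname(b[1]),
    sse = best$sse, sse_line = one$sse,
    improvement = improvement,
    material = improvement >= 0.01,
    n = n), class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(
    "<breakpoint_fit> break at %.0f m; slopes %.4f / %.4f per km (n=%d)%s\n",
    x$breakpoint_m, x$slope_pre, x$slope_post, x$n,
    if (x$material) "" else " [no material breakpoint]"))
  invisible(x)
}

#' Elevation-band profile of the potential surface
#'
#' Mean index and area within half-open elevation bands
#' `[k*w, (k+1)*w)` spanning the DEM range; empty bands are omitted.
#'
#' @param pm a `potential_map`.
#' @param dem aligned elevation [raster_grid()] (m).
#' @param band_width_m band width in meters (default 50).
#' @return data.frame with `band_lo_m`, `band_hi_m`, `mean_inrpi`,
#'   `area_km2`.
#' @export
band_profile <- function(pm, dem, band_width_m = 50) {
  stopifnot(inherits(pm, "potential_map"), is_raster_grid(dem),
            band_width_m > 0)
  stop_if_grid_mismatch(pm$grid, dem, "potential map and DEM")
  ok <- !is.na(pm$grid$values) & !is.na(dem$values)
  e <- dem$values[ok]; v <- pm$grid$values[ok]
  k <- floor(e / band_width_m)
  a <- cell_area_km2(pm$grid)
  agg_mean <- tapply(v, k, mean)
  agg_n <- tapply(v, k, length)
  ks <- as.numeric(names(agg_mean))
  out <- data.frame(band_lo_m = ks * band_width_m,
                    band_hi_m = (ks + 1) * band_width_m,
                    mean_inrpi = as.numeric(agg_mean),
                    area_km2 = as.numeric(agg_n) * a)
  out[order(out$band_lo_m), , drop = FALSE]
}
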