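#' Configuration of a synthetic landscape
#'
#' The generator's world: a rectangular 1 km grid with a SE-to-NW elevation
#' ramp, a latent recreation-suitability surface that rises gently with
#' elevation up to a planted threshold and then decays linearly, 15 indicator
#' layers that are affine images of that latent surface in plausible native
#' units, an elevation-graded categorical land cover, random feature sets for
#' the distance layers, and protected-area / division-line zones.
#'
#' @param nrow,ncol grid shape in cells.
#' @param cellsize cell size in meters.
#' @param elev_range `c(min, max)` elevation in meters, low in the SE corner.
#' @param elev_noise_sd sd (m) of the smooth terrain perturbation field.
#' @param elev_corlen correlation length (cells) of that field.
#' @param threshold_m planted elevation threshold T (m) of the suitability
#'   break; must lie inside `elev_range`.
#' @param slope_pre latent suitability slope below T, per 1000 m.
#' @param slope_post latent slope above T, per 1000 m (negative: potential
#'   decays with altitude past the threshold).
#' @param base_potential latent suitability at the elevation minimum.
#' @param noise_sd sd of the shared per-cell noise on the latent surface —
#'   this is the noise level the recovered index inherits.
#' @param field_sd sd of each indicator's own smooth (spatially correlated)
#'   deviation field.
#' @param corlen correlation length (cells) of the indicator fields; scalar
#'   or named per-code vector.
#' @param epochs epoch labels (default 2000/2010/2020).
#' @param drift_base latent baseline drift added per successive epoch.
#' @param drift_threshold_m threshold drift (m) per successive epoch.
#' @param n_lakes,n_rivers,n_glaciers,n_counties feature counts.
#' @param pa_fraction target protected-area share of the grid, in (0,1).
#' @param n_lc_classes number of land-cover classes.
#' @param indicator_ranges optional named list code -> `c(lo, hi)` native
#'   range overrides.
#' @param seed RNG seed; the full bundle is reproducible from it.
#' @export
landscape_config <- function(nrow = 120, ncol = 120, cellsize = 1000,
                             elev_range = c(1000, 5500),
                             elev_noise_sd = 150, elev_corlen = 10,
                             threshold_m = 3000, slope_pre = 0.02,
                             slope_post = -0.30, base_potential = 0.80,
                             noise_sd = 0.03, field_sd = 0.05, corlen = 8,
                             epochs = c(2000, 2010, 2020),
                             drift_base = 0.005, drift_threshold_m = 25,
                             n_lakes = 8, n_rivers = 5, n_glaciers = 6,
                             n_counties = 10, pa_fraction = 0.25,
                             n_lc_classes = 6, indicator_ranges = NULL,
                             seed = 1L) {
  stopifnot(nrow >= 8, ncol >= 8, cellsize > 0,
            length(elev_range) == 2, diff(elev_range) > 0,
            elev_noise_sd >= 0, elev_corlen >= 1,
            noise_sd >= 0, field_sd >= 0, all(corlen >= 1),
            length(epochs) >= 1,
            n_lakes >= 1, n_rivers >= 0, n_glaciers >= 1, n_counties >= 1,
            pa_fraction > 0, pa_fraction < 1, n_lc_classes >= 2)
  if (threshold_m <= elev_range[1] || threshold_m >= elev_range[2])
    stop("threshold_m must lie strictly inside elev_range", call. = FALSE)
  if (n_lakes + n_counties + n_glaciers > nrow * ncol)
    stop("more point features requested than grid cells", call. = FALSE)
  structure(as.list(environment()), class = "landscape_config")
}

# native-unit affine ranges per indicator (lo, hi); latent 0 maps to the
# "worst" end given polarity, latent 1 to the "best" end
default_indicator_ranges <- function() {
  list(
    SHDI = c(0, 1.8),      RDLS = c(0, 6),        HQ  = c(0, 1),
    DTPA = c(0, 2e5),      NDVI = c(0, 0.9),      DTL = c(0, 1.5e5),
    DTR  = c(0, 1e5),      DTG  = c(0, 2.5e5),    OC  = c(150, 300),
    PRRI = c(20, 80),      TEM  = c(-15, 10),     PRE = c(50, 800),
    TNI  = c(0.5, 2),      DTC  = c(0, 1.2e5),    TA  = c(2, 48))
}

# smooth unit-variance field: Gaussian-filtered white noise, standardized
gaussian_field <- function(nr, nc, corlen) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corlen <= 1) {
    f <- w
  } else {
    s <- corlen / 2
    half <- ceiling(3 * s)
    k <- stats::dnorm(seq(-half, half), sd = s)
    band <- function(n) {
      B <- matrix(0, n, n)
      i <- seq_len(n)
      for (d in seq(-half, half)) {
        j <- i + d
        ok <- j >= 1 & j <= n
        B[cbind(i[ok], j[ok])] <- k[d + half + 1]
      }
      B / rowSums(B)  # edge renormalization
    }
    f <- band(nr) %*% w %*% t(band(nc))
  }
  (f - mean(f)) / stats::sd(f)
}

# SE -> NW ramp in [0,1]: 0 at the SE corner (last row/col), 1 at NW
ramp_matrix <- function(nr, nc) {
  outer(seq_len(nr), seq_len(nc),
        function(i, j) ((nr - i) + (nc - j)) / (nr + nc - 2))
}

# piecewise-linear latent suitability vs elevation for epoch k (1-based)
latent_mu <- function(elev, cfg, k = 1L) {
  base <- cfg$base_potential + (k - 1) * cfg$drift_base
  Tm <- cfg$threshold_m + (k - 1) * cfg$drift_threshold_m
  e0 <- cfg$elev_range[1]
  pre <- base + cfg$slope_pre * (pmin(elev, Tm) - e0) / 1000
  post <- cfg$slope_post * pmax(elev - Tm, 0) / 1000
  pre + post
}

#' Planted generative parameters of a landscape configuration
#'
#' The deterministic ground truth a parameter-recovery test asserts against:
#' per-epoch threshold and latent slopes, the affine native ranges of every
#' indicator (which double as the supplied min/max standardization table),
#' and the land-cover mixture rule.
#'
#' @param cfg a [landscape_config()].
#' @return list with `threshold_m` (per epoch), `slope_pre`, `slope_post`,
#'   `base_potential` (per epoch), `minmax` (code -> c(min, max)),
#'   `ranges`, `polarity`, `noise_sd`, `field_sd`, `config`.
#' @export
expected_truth <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  ranges <- default_indicator_ranges()
  if (!is.null(cfg$indicator_ranges))
    ranges[names(cfg$indicator_ranges)] <- cfg$indicator_ranges
  reg <- indicator_registry()
  minmax <- stats::setNames(lapply(reg$code, function(code) {
    r <- ranges[[code]]
    c(r[1], r[2])
  }), reg$code)
  nk <- length(cfg$epochs)
  list(
    threshold_m = stats::setNames(
      cfg$threshold_m + (seq_len(nk) - 1) * cfg$drift_threshold_m,
      cfg$epochs),
    slope_pre = cfg$slope_pre, slope_post = cfg$slope_post,
    base_potential = stats::setNames(
      cfg$base_potential + (seq_len(nk) - 1) * cfg$drift_base, cfg$epochs),
    minmax = minmax, ranges = ranges,
    polarity = stats::setNames(reg$polarity, reg$code),
    noise_sd = cfg$noise_sd, field_sd = cfg$field_sd,
    config = cfg)
}

#' Generate a complete synthetic input bundle
#'
#' Builds, reproducibly from `cfg$seed`: a DEM (SE->NW ramp plus smooth
#' bumps), one 15-layer indicator stack per epoch, an elevation-graded land
#' cover, point/line/polygon feature sets (lakes, rivers, glaciers, counties,
#' protected areas), and zone masks (PA/NPA and the SE/NW halves of the
#' grid's dividing line).
#'
#' Every indicator is an affine image, in native units, of one latent surface
#' `mu(elevation) + shared cell noise + own smooth field`, with the sign set
#' by its polarity. Standardizing with the generator's exported min/max
#' table ([expected_truth()]`$minmax`) therefore turns each layer back into
#' `latent` (clipped to [0,1]), and any weighted overlay with weights summing
#' to 1 returns `mu + noise` — which is what makes the planted threshold and
#' post-break slope recoverable by the segmented regression.
#'
#' @param cfg a [landscape_config()].
#' @return list with `stacks` (named by epoch), `dem`, `landcover`,
#'   `features` (named list of [feature_set()]s), `zones` ([zone_set()]),
#'   `truth` (as [expected_truth()], plus the realized protected-area
#'   rectangles).
#' @export
generate_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  truth <- expected_truth(cfg)
  withr::with_seed(cfg$seed, {
    nr <- cfg$nrow; nc <- cfg$ncol; cs <- cfg$cellsize
    template <- raster_grid(matrix(0, nr, nc), cs)
    cc <- cell_centers(template)

    # --- terrain -----------------------------------------------------------
    tramp <- ramp_matrix(nr, nc)
    elev <- cfg$elev_range[1] + tramp * diff(cfg$elev_range)
    if (cfg$elev_noise_sd > 0)
      elev <- elev + cfg$elev_noise_sd * gaussian_field(nr, nc, cfg$elev_corlen)
    elev <- pmin(pmax(elev, cfg$elev_range[1]), cfg$elev_range[2])
    dem <- raster_grid(elev, cs)

    # --- indicator stacks --------------------------------------------------
    reg <- indicator_registry()
    corlen <- cfg$corlen
    cl_for <- function(code)
      if (length(corlen) > 1L && code %in% names(corlen)) corlen[[code]]
      else corlen[[1]]
    own_fields <- stats::setNames(
      lapply(reg$code, function(code) gaussian_field(nr, nc, cl_for(code))),
      reg$code)
    stacks <- list()
    for (k in seq_along(cfg$epochs)) {
      eps <- if (cfg$noise_sd > 0)
        matrix(stats::rnorm(nr * nc, sd = cfg$noise_sd), nr, nc)
      else matrix(0, nr, nc)
      mu <- latent_mu(elev, cfg, k)
      layers <- lapply(seq_len(nrow(reg)), function(i) {
        code <- reg$code[i]
        latent <- mu + eps + cfg$field_sd * own_fields[[code]]
        r <- truth$ranges[[code]]
        x <- if (reg$polarity[i] == "positive")
          r[1] + (r[2] - r[1]) * latent
        else r[2] - (r[2] - r[1]) * latent
        indicator_layer(code, raster_grid(x, cs))
      })
      stacks[[as.character(cfg$epochs[k])]] <-
        indicator_stack(layers, epoch = cfg$epochs[k], complete = TRUE)
    }

    # --- land cover: mixture concentrates with altitude --------------------
    u <- (elev - cfg$elev_range[1]) / diff(cfg$elev_range)
    K <- cfg$n_lc_classes
    lc <- matrix(NA_real_, nr, nc)
    beta <- 4 * as.vector(u)
    logits <- -outer(beta, seq_len(K) - 1)
    p <- exp(logits); p <- p / rowSums(p)
    cum <- t(apply(p, 1, cumsum))
    rn <- stats::runif(nr * nc)
    lc[] <- 1L + rowSums(cum < rn)
    landcover <- land_cover_grid(raster_grid(lc, cs))

    # --- features ----------------------------------------------------------
    cell_xy <- function(idx) {
      i <- (idx - 1L) %% nr + 1L
      j <- (idx - 1L) %/% nr + 1L
      cbind(cc$x[j], cc$y[i])
    }
    rand_cells <- function(n, prob = NULL) sample(nr * nc, n, prob = prob)
    jitter_xy <- function(xy) xy + matrix(stats::runif(length(xy), -cs / 4,
                                                       cs / 4), ncol = 2)
    lakes <- feature_set("lakes",
                         points = jitter_xy(cell_xy(rand_cells(cfg$n_lakes))))
    # glaciers sit at the highest cells
    gl_idx <- order(as.vector(elev), decreasing = TRUE)[seq_len(cfg$n_glaciers)]
    glaciers <- feature_set("glaciers", points = jitter_xy(cell_xy(gl_idx)))
    # counties favour low elevation
    cty_idx <- rand_cells(cfg$n_counties, prob = exp(-3 * as.vector(u)))
    counties <- feature_set("counties", points = jitter_xy(cell_xy(cty_idx)))
    rivers <- NULL
    if (cfg$n_rivers > 0) {
      mk_river <- function() {
        start <- cell_xy(rand_cells(1))
        steps <- 15L
        ang <- stats::runif(1, 0, 2 * pi) +
          cumsum(stats::rnorm(steps, sd = 0.4))
        pts <- rbind(start,
                     start[rep(1, steps), , drop = FALSE] +
                       cbind(cumsum(cos(ang)), cumsum(sin(ang))) * 2.5 * cs)
        pts
      }
      rivers <- feature_set("rivers",
                            lines = lapply(seq_len(cfg$n_rivers),
                                           function(i) mk_river()))
    }

    # --- protected areas: square blocks seeded at attractive cells ---------
    mu1 <- latent_mu(elev, cfg, 1L)
    target <- cfg$pa_fraction * nr * nc
    side <- max(3L, round(sqrt(target / 8)))
    pa_mask <- matrix(FALSE, nr, nc)
    ord <- order(as.vector(mu1 + 0.05 * gaussian_field(nr, nc, 6)),
                 decreasing = TRUE)
    rects <- list()
    for (idx in ord) {
      if (sum(pa_mask) >= target) break
      i <- (idx - 1L) %% nr + 1L; j <- (idx - 1L) %/% nr + 1L
      if (pa_mask[i, j]) next
      i0 <- max(1L, i - side %/% 2L); i1 <- min(nr, i0 + side - 1L)
      j0 <- max(1L, j - side %/% 2L); j1 <- min(nc, j0 + side - 1L)
      pa_mask[i0:i1, j0:j1] <- TRUE
      # rectangle in map coordinates (cell edges)
      x0 <- template$xmin + (j0 - 1) * cs; x1 <- template$xmin + j1 * cs
      y1 <- template$ymax - (i0 - 1) * cs; y0 <- template$ymax - i1 * cs
      rects[[length(rects) + 1L]] <-
        cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))
    }
    pas <- feature_set("protected_areas", polygons = rects)

    zones <- zone_set(list(
      PA = pa_mask, NPA = !pa_mask,
      SE_of_line = tramp < 0.5, NW_of_line = tramp >= 0.5), template)

    truth$pa_rectangles <- rects
    list(stacks = stacks, dem = dem, landcover = landcover,
         features = list(lakes = lakes, rivers = rivers, glaciers = glaciers,
                         counties = counties, protected_areas = pas),
         zones = zones, truth = truth)
  })
}

#' Write a generated bundle to a run directory
#'
#' Serializes every raster as an ESRI ASCII grid, features as GeoJSON and
#' zone masks as 0/1 rasters, so the command-line stages can consume the
#' bundle from disk.
#'
#' @param bundle output of [generate_landscape()].
#' @param dir output directory (created if needed).
#' @export
write_landscape <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raster(bundle$dem, file.path(dir, "dem.asc"))
  write_raster(bundle$landcover$grid, file.path(dir, "landcover.asc"))
  for (ep in names(bundle$stacks)) {
    st <- bundle$stacks[[ep]]
    for (code in names(st$layers))
      write_raster(st$layers[[code]]$grid,
                   file.path(dir, sprintf("%s_%s.asc", code, ep)))
  }
  for (nm in names(bundle$features))
    if (!is.null(bundle$features[[nm]]))
      write_features(bundle$features[[nm]], file.path(dir, paste0(nm,
                                                                  ".geojson")))
  tmpl <- bundle$zones$template
  for (nm in names(bundle$zones$masks))
    write_raster(raster_grid(bundle$zones$masks[[nm]] + 0, tmpl$cellsize,
                             tmpl$xmin, tmpl$ymax, tmpl$crs),
                 file.path(dir, sprintf("zone_%s.asc", nm)))
  mm <- bundle$truth$minmax
  utils::write.csv(
    data.frame(code = names(mm),
               min = vapply(mm, `[`, 0, 1), max = vapply(mm, `[`, 0, 2)),
    file.path(dir, "minmax.csv"), row.names = FALSE)
  invisible(dir)
}
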