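#' Indicator registry
#'
#' The 15 evaluation indicators of the recreation-potential index, grouped by
#' criterion, with their fixed polarity. Polarity governs standardization
#' direction: for a positive indicator larger raw values mean more potential;
#' for a negative indicator (distances, altitude-sickness risk, terrain niche,
#' travel time) smaller raw values mean more potential.
#'
#' @return data.frame with columns `code`, `polarity` (`"positive"` /
#'   `"negative"`), `criterion`, `units`.
#' @export
indicator_registry <- function() {
  data.frame(
    code = c("SHDI", "RDLS", "HQ", "DTPA", "NDVI", "DTL", "DTR", "DTG",
             "OC", "PRRI", "TEM", "PRE", "TNI", "DTC", "TA"),
    polarity = c("positive", "positive", "positive", "negative", "positive",
                 "negative", "negative", "negative", "positive", "negative",
                 "positive", "positive", "negative", "negative", "negative"),
    criterion = c(rep("resources", 3), rep("attractiveness", 5),
                  rep("comfort_opportunity", 5), rep("reception", 2)),
    units = c("", "", "", "m", "", "m", "m", "m", "g/m3", "%",
              "degC", "mm", "", "m", "h"),
    stringsAsFactors = FALSE)
}

indicator_codes <- function() indicator_registry()$code

registry_polarity <- function(code) {
  reg <- indicator_registry()
  i <- match(code, reg$code)
  if (is.na(i)) stop("unknown indicator code: ", code, call. = FALSE)
  reg$polarity[i]
}

#' Construct an indicator layer
#'
#' Wraps one raster as a named evaluation indicator. The polarity, when given,
#' must agree with the registry; when omitted it is looked up.
#'
#' @param code one of the 15 registry codes.
#' @param grid a [raster_grid()].
#' @param polarity optional `"positive"` or `"negative"`; checked against the
#'   registry.
#' @param units free-text units (default from the registry).
#' @export
indicator_layer <- function(code, grid, polarity = NULL, units = NULL) {
  stopifnot(is_raster_grid(grid))
  expected <- registry_polarity(code)
  if (!is.null(polarity)) {
    polarity <- match.arg(polarity, c("positive", "negative"))
    if (polarity != expected)
      stop("indicator ", code, " is a ", expected,
           " indicator; polarity '", polarity, "' contradicts the registry",
           call. = FALSE)
  }
  reg <- indicator_registry()
  if (is.null(units)) units <- reg$units[match(code, reg$code)]
  structure(list(code = code, polarity = expected, grid = grid,
                 units = units),
            class = "indicator_layer")
}

#' Register an externally computed indicator layer
#'
#' Entry point for indicators whose formulas live outside this package
#' (terrain ruggedness, habitat quality, oxygen content, altitude-sickness
#' risk, terrain niche, travel time, climate fields): the raster joins the
#' stack unmodified after code/polarity validation.
#'
#' @inheritParams indicator_layer
#' @export
register_external_layer <- function(code, grid, polarity = NULL) {
  indicator_layer(code, grid, polarity = polarity)
}

#' Bundle indicator layers into an epoch stack
#'
#' @param layers list of [indicator_layer()]s with unique codes, all on one
#'   grid.
#' @param epoch epoch label (e.g. `2000`).
#' @param complete require all 15 registry codes (needed for the overlay;
#'   subsets are allowed for intermediate work).
#' @export
indicator_stack <- function(layers, epoch = "epoch0", complete = FALSE) {
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, TRUE, "indicator_layer")))
  codes <- vapply(layers, `[[`, "", "code")
  if (anyDuplicated(codes))
    stop("duplicate indicator codes in stack: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  if (complete && !setequal(codes, indicator_codes()))
    stop("stack must contain all 15 indicators; missing: ",
         paste(setdiff(indicator_codes(), codes), collapse = ", "),
         call. = FALSE)
  g0 <- layers[[1]]$grid
  for (l in layers[-1]) stop_if_grid_mismatch(g0, l$grid, "stack layers")
  names(layers) <- codes
  structure(list(epoch = epoch, layers = layers), class = "indicator_stack")
}

#' @export
print.indicator_stack <- function(x, ...) {
  cat(sprintf("<indicator_stack> epoch %s, %d layers: %s\n", x$epoch,
              length(x$layers), paste(names(x$layers), collapse = " ")))
  invisible(x)
}

#' Align indicator layers onto a common template grid
#'
#' Resamples each layer onto the template (cell-center lookup) and propagates
#' the union of input nodata: a cell masked in any input is masked in every
#' output layer, so the overlay is only defined where all indicators are.
#'
#' @param layers list of [indicator_layer()]s.
#' @param template [raster_grid()] supplying the target geometry.
#' @param resampling `"nearest"` or `"bilinear"`; categorical layers (class
#'   `land_cover_grid` inputs) must use `"nearest"`.
#' @param epoch epoch label for the resulting stack.
#' @param categorical character vector of codes to force nearest-neighbour.
#' @return an [indicator_stack()] on the template grid.
#' @export
align_stack <- function(layers, template,
                        resampling = c("nearest", "bilinear"),
                        epoch = "epoch0", categorical = character()) {
  resampling <- match.arg(resampling)
  if (resampling == "bilinear" && length(categorical))
    stop("categorical layers (", paste(categorical, collapse = ", "),
         ") cannot be resampled bilinearly", call. = FALSE)
  res <- lapply(layers, function(l)
    indicator_layer(l$code, resample_grid(l$grid, template, resampling),
                    units = l$units))
  # union-of-masks nodata propagation
  bad <- Reduce(`|`, lapply(res, function(l) is.na(l$grid$values)))
  res <- lapply(res, function(l) {
    l$grid$values[bad] <- NA_real_
    l
  })
  indicator_stack(res, epoch = epoch)
}

#' Categorical land-cover raster
#'
#' @param grid [raster_grid()] holding small-integer class codes.
#' @param legend named character vector mapping code -> class name.
#' @export
land_cover_grid <- function(grid, legend = NULL) {
  stopifnot(is_raster_grid(grid))
  v <- grid$values[!is.na(grid$values)]
  if (length(v) && any(v != round(v)))
    stop("land cover classes must be integer codes", call. = FALSE)
  if (is.null(legend)) {
    cls <- sort(unique(v))
    legend <- stats::setNames(paste0("class_", cls), cls)
  }
  if (length(v) && !all(as.character(sort(unique(v))) %in% names(legend)))
    stop("land cover contains codes missing from the legend", call. = FALSE)
  structure(list(grid = grid, legend = legend), class = "land_cover_grid")
}

#' Geometry collection for distance layers
#'
#' @param name collection name (lakes, rivers, glaciers, counties,
#'   protected_areas, ...).
#' @param points optional n x 2 matrix of projected coordinates.
#' @param lines list of polylines (m x 2 matrices).
#' @param polygons list of closed outer rings (m x 2 matrices; first and last
#'   vertex may coincide but need not).
#' @param crs CRS identifier; must match the template grid's.
#' @export
feature_set <- function(name, points = NULL, lines = list(),
                        polygons = list(), crs = "local-metric") {
  if (!is.null(points)) {
    points <- matrix(as.numeric(points), ncol = 2)
  }
  n <- (if (is.null(points)) 0L else nrow(points)) + length(lines) +
    length(polygons)
  if (n == 0L) stop("feature set '", name, "' is empty", call. = FALSE)
  structure(list(name = name, points = points, lines = lines,
                 polygons = polygons, crs = crs),
            class = "feature_set")
}

#' Named zones for zonal statistics
#'
#' Zones are boolean masks co-registered with the analysis grid. Polygons can
#' be rasterized onto the template with [polygon_mask()] first.
#'
#' @param masks named list of logical matrices (TRUE = in zone), all the
#'   shape of the template.
#' @param template [raster_grid()] the masks are registered to.
#' @export
zone_set <- function(masks, template) {
  stopifnot(is.list(masks), length(masks) >= 1L, !is.null(names(masks)),
            is_raster_grid(template))
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !all(dim(m) == dim(template$values)))
      stop("zone '", nm, "' is not a logical mask on the template grid",
           call. = FALSE)
  }
  structure(list(masks = masks, template = template), class = "zone_set")
}

#' Rasterize a polygon set to a boolean mask
#'
#' Even-odd (crossing-number) point-in-polygon test of each cell center
#' against every ring; a cell is in the mask when its center is inside any
#' ring.
#'
#' @param polygons list of rings (m x 2 matrices) or a [feature_set()].
#' @param template [raster_grid()].
#' @return logical matrix shaped like the template.
#' @export
polygon_mask <- function(polygons, template) {
  if (inherits(polygons, "feature_set")) polygons <- polygons$polygons
  stopifnot(length(polygons) >= 1L)
  cc <- cell_centers(template)
  nr <- nrow(template$values); nc <- ncol(template$values)
  px <- rep(cc$x, each = nr)
  py <- rep(cc$y, times = nc)
  inside <- rep(FALSE, nr * nc)
  for (ring in polygons) {
    rx <- ring[, 1]; ry <- ring[, 2]
    m <- nrow(ring)
    if (rx[1] == rx[m] && ry[1] == ry[m]) { rx <- rx[-m]; ry <- ry[-m]; m <- m - 1L }
    cross <- rep(0L, nr * nc)
    jprev <- m
    for (j in seq_len(m)) {
      x1 <- rx[jprev]; y1 <- ry[jprev]; x2 <- rx[j]; y2 <- ry[j]
      hit <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      cross <- cross + as.integer(hit)
      jprev <- j
    }
    inside <- inside | (cross %% 2L == 1L)
  }
  matrix(inside, nrow = nr, ncol = nc)
}
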