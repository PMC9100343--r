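# pull the (min,max) pair for a code out of a minmax table (named list of
# length-2 vectors, or a 2-column matrix/data.frame with code rownames);
# NULL when absent
minmax_for <- function(minmax, code) {
  if (is.null(minmax)) return(NULL)
  if (is.list(minmax) && !is.data.frame(minmax)) {
    mm <- minmax[[code]]
  } else {
    mm <- if (code %in% rownames(minmax)) as.numeric(minmax[code, 1:2]) else NULL
  }
  if (is.null(mm)) return(NULL)
  as.numeric(mm)
}

#' Polarity-aware min-max standardization
#'
#' Positive indicators map linearly so the layer maximum scores 1; negative
#' indicators are reversed so the layer minimum scores 1:
#' positive: Xs = (x - min) / (max - min);
#' negative: Xs = (max - x) / (max - min).
#' When `minmax` is supplied (e.g. a range pooled over epochs so scores stay
#' comparable through time), out-of-range inputs clip to [0,1].
#'
#' @param layer an [indicator_layer()].
#' @param minmax optional `c(min, max)` to use instead of the layer's own
#'   valid-cell range.
#' @return a [raster_grid()] of standardized scores in [0,1].
#' @export
standardize <- function(layer, minmax = NULL) {
  stopifnot(inherits(layer, "indicator_layer"))
  v <- layer$grid$values
  supplied <- !is.null(minmax)
  if (supplied) {
    lo <- minmax[1]; hi <- minmax[2]
  } else {
    ok <- v[!is.na(v)]
    if (!length(ok)) stop("indicator ", layer$code, " has no valid cells",
                          call. = FALSE)
    lo <- min(ok); hi <- max(ok)
  }
  if (!(hi > lo))
    stop("indicator ", layer$code,
         " is constant over valid cells; supply an explicit minmax range",
         call. = FALSE)
  s <- if (layer$polarity == "positive") (v - lo) / (hi - lo)
       else (hi - v) / (hi - lo)
  if (supplied) s <- pmin(pmax(s, 0), 1)
  g <- layer$grid
  raster_grid(s, g$cellsize, g$xmin, g$ymax, g$crs)
}

#' Min/max table pooled across epochs
#'
#' Per indicator, the min and max of raw values over the valid cells of every
#' stack supplied — the "global" standardization policy that keeps the index
#' on one scale through time.
#'
#' @param stacks list of [indicator_stack()]s (e.g. one per epoch).
#' @return named list code -> `c(min, max)`.
#' @export
global_minmax <- function(stacks) {
  stopifnot(length(stacks) >= 1L)
  codes <- names(stacks[[1]]$layers)
  out <- list()
  for (code in codes) {
    lo <- Inf; hi <- -Inf
    for (st in stacks) {
      v <- st$layers[[code]]$grid$values
      v <- v[!is.na(v)]
      if (length(v)) { lo <- min(lo, v); hi <- max(hi, v) }
    }
    out[[code]] <- c(lo, hi)
  }
  out
}

#' Weighted-overlay recreation potential surface
#'
#' The integrated potential index per cell is the convex combination
#' INRPI = sum_j W_j * Xs_j of the 15 polarity-standardized indicator scores,
#' so it lies in [0,1] and is nodata wherever any indicator is nodata.
#'
#' @param stack a complete (15-code) [indicator_stack()].
#' @param weights a [weight_set()] of kind `"combined"` covering all codes.
#' @param minmax_policy `"per_epoch"` (ranges from this stack's valid cells)
#'   or `"global"` (ranges from `minmax`, pooled elsewhere, e.g. with
#'   [global_minmax()]).
#' @param minmax min/max table (named list code -> c(min, max)); required for
#'   the `"global"` policy.
#' @return a `potential_map`: fields `grid`, `epoch`, `weights_used`,
#'   `minmax_table` (the ranges actually applied), `minmax_policy`.
#' @export
compute_inrpi <- function(stack, weights,
                          minmax_policy = c("per_epoch", "global"),
                          minmax = NULL) {
  minmax_policy <- match.arg(minmax_policy)
  stopifnot(inherits(stack, "indicator_stack"),
            inherits(weights, "weight_set"))
  codes <- indicator_codes()
  missing <- setdiff(codes, names(stack$layers))
  if (length(missing))
    stop("stack is missing indicators: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!setequal(names(weights$weights), codes))
    stop("weight set does not cover the 15 indicator codes", call. = FALSE)
  if (minmax_policy == "global" && is.null(minmax))
    stop("global minmax policy requires a pooled minmax table", call. = FALSE)
  g0 <- stack$layers[[1]]$grid
  acc <- matrix(0, nrow(g0$values), ncol(g0$values))
  bad <- matrix(FALSE, nrow(g0$values), ncol(g0$values))
  table_used <- list()
  for (code in codes) {
    layer <- stack$layers[[code]]
    mm <- if (minmax_policy == "global") minmax_for(minmax, code)
          else minmax_for(minmax, code)  # per_epoch may still pin single layers
    s <- standardize(layer, minmax = mm)
    if (is.null(mm)) {
      v <- layer$grid$values[!is.na(layer$grid$values)]
      mm <- c(min(v), max(v))
    }
    table_used[[code]] <- mm
    sv <- s$values
    bad <- bad | is.na(sv)
    sv[is.na(sv)] <- 0
    acc <- acc + weights$weights[[code]] * sv
  }
  acc[bad] <- NA_real_
  structure(
    list(grid = raster_grid(acc, g0$cellsize, g0$xmin, g0$ymax, g0$crs),
         epoch = stack$epoch, weights_used = weights,
         minmax_table = table_used, minmax_policy = minmax_policy),
    class = "potential_map")
}

#' @export
print.potential_map <- function(x, ...) {
  cat(sprintf("<potential_map> epoch %s (%s minmax)\n", x$epoch,
              x$minmax_policy))
  print(x$grid)
  invisible(x)
}

default_level_labels <- function(K) {
  if (K == 5)
    c("very low", "low", "moderate", "high", "very high")
  else paste0("L", seq_len(K))
}

# geometric-series breakpoints b_k = mn + a (g^k - 1)/(g - 1), a set so
# b_K = mx; g chosen by 1-D search minimizing within-class squared deviation
geometric_interval_breaks <- function(values, K) {
  mn <- min(values); mx <- max(values)
  breaks_for <- function(g) {
    k <- seq_len(K - 1)
    if (abs(g - 1) < 1e-9) mn + (mx - mn) * k / K
    else mn + (mx - mn) * (g^k - 1) / (g^K - 1)
  }
  wss <- function(g) {
    b <- breaks_for(g)
    cls <- findInterval(values, b, left.open = FALSE) + 1L
    s <- 0
    for (c in unique(cls)) {
      v <- values[cls == c]
      s <- s + sum((v - mean(v))^2)
    }
    s
  }
  opt <- stats::optimize(function(lg) wss(exp(lg)), interval = c(-3, 3))
  g <- exp(opt$minimum)
  list(breaks = breaks_for(g), ratio = g)
}

#' Cut a potential surface into ordinal levels
#'
#' Either with supplied breakpoints (`mode = "fixed"`) or with data-driven
#' geometric-interval breakpoints, whose class widths form a geometric series
#' spanning the valid-value range with the common ratio chosen to minimize
#' total within-class squared deviation. Bins are left-closed/right-open;
#' the top class is closed, so a value equal to an interior breakpoint falls
#' in the class above it.
#'
#' @param pm a `potential_map` (or bare [raster_grid()]).
#' @param mode `"fixed"` or `"geometric_interval"`.
#' @param K number of levels (>= 2), default 5.
#' @param fixed_breaks ascending numeric of length `K - 1` (fixed mode).
#' @param labels level names; sensible defaults for K = 5.
#' @return a `class_map`: integer grid 1..K, `breakpoints`, `labels`.
#' @export
classify <- function(pm, mode = c("fixed", "geometric_interval"), K = 5,
                     fixed_breaks = NULL, labels = NULL) {
  mode <- match.arg(mode)
  grid <- if (inherits(pm, "potential_map")) pm$grid else pm
  stopifnot(is_raster_grid(grid), K >= 2)
  v <- grid$values
  ok <- !is.na(v)
  if (!any(ok)) stop("no valid cells to classify", call. = FALSE)
  if (mode == "fixed") {
    if (is.null(fixed_breaks) || length(fixed_breaks) != K - 1)
      stop("fixed mode needs K - 1 = ", K - 1, " breakpoints", call. = FALSE)
    if (is.unsorted(fixed_breaks, strictly = TRUE))
      stop("breakpoints must be strictly increasing", call. = FALSE)
    breaks <- as.numeric(fixed_breaks)
    if (min(v[ok]) > max(breaks) || max(v[ok]) < min(breaks))
      warning("breakpoints lie outside the data range; some classes empty")
    ratio <- NA_real_
  } else {
    gi <- geometric_interval_breaks(v[ok], K)
    breaks <- gi$breaks
    ratio <- gi$ratio
  }
  cls <- matrix(NA_integer_, nrow(v), ncol(v))
  cls[ok] <- findInterval(v[ok], breaks, left.open = FALSE) + 1L
  if (is.null(labels)) labels <- default_level_labels(K)
  structure(
    list(grid = raster_grid(cls, grid$cellsize, grid$xmin, grid$ymax,
                            grid$crs),
         breakpoints = breaks, labels = labels, K = as.integer(K),
         ratio = ratio,
         epoch = if (inherits(pm, "potential_map")) pm$epoch else NULL),
    class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat(sprintf("<class_map> K=%d, breaks: %s\n", x$K,
              paste(signif(x$breakpoints, 4), collapse = ", ")))
  invisible(x)
}
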