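#' Per-level areas of a class map
#'
#' @param cm a `class_map` from [classify()].
#' @param mask optional logical matrix restricting the tally to a zone.
#' @return named numeric vector of areas in km^2, one entry per level 1..K
#'   (zeros kept).
#' @export
level_areas <- function(cm, mask = NULL) {
  stopifnot(inherits(cm, "class_map"))
  v <- cm$grid$values
  if (!is.null(mask)) v[!mask] <- NA_integer_
  a <- cell_area_km2(cm$grid)
  counts <- tabulate(v[!is.na(v)], nbins = cm$K)
  stats::setNames(counts * a, as.character(seq_len(cm$K)))
}

#' Level transition matrix between two epochs
#'
#' Cross-tabulates areas (km^2) by class at the first and second epoch over
#' cells valid at both; cells valid in only one epoch are excluded and their
#' area reported in `dropped_km2`.
#'
#' @param c1,c2 `class_map`s on the same grid with the same `K`.
#' @return a `transition_matrix`: `areas` (K x K km^2, rows = from-class),
#'   `from_epoch`, `to_epoch`, `class_labels`, `dropped_km2`.
#' @export
transition_matrix <- function(c1, c2) {
  stopifnot(inherits(c1, "class_map"), inherits(c2, "class_map"))
  stop_if_grid_mismatch(c1$grid, c2$grid, "class maps")
  if (c1$K != c2$K) stop("class maps use different numbers of levels",
                         call. = FALSE)
  v1 <- c1$grid$values; v2 <- c2$grid$values
  both <- !is.na(v1) & !is.na(v2)
  a <- cell_area_km2(c1$grid)
  K <- c1$K
  tab <- table(factor(v1[both], levels = seq_len(K)),
               factor(v2[both], levels = seq_len(K)))
  areas <- matrix(as.numeric(tab), K, K,
                  dimnames = list(from = c1$labels, to = c2$labels)) * a
  dropped <- sum(xor(is.na(v1), is.na(v2))) * a
  structure(list(areas = areas, from_epoch = c1$epoch, to_epoch = c2$epoch,
                 class_labels = c1$labels, dropped_km2 = dropped),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %s -> %s (km^2)\n",
              x$from_epoch, x$to_epoch))
  print(round(x$areas, 2))
  invisible(x)
}

#' Zonal summary of a potential surface and its level map
#'
#' Per zone: valid area, area-weighted mean index, and per-level areas and
#' proportions. An empty zone is kept with zero area and `NA` mean.
#'
#' @param pm a `potential_map`.
#' @param cm the matching `class_map`.
#' @param zones a [zone_set()] co-registered with `pm`.
#' @return list with data.frames `means` (zone, epoch, area_km2, mean_inrpi)
#'   and `levels` (zone, level, label, area_km2, proportion).
#' @export
zone_summary <- function(pm, cm, zones) {
  stopifnot(inherits(pm, "potential_map"), inherits(cm, "class_map"),
            inherits(zones, "zone_set"))
  stop_if_grid_mismatch(pm$grid, cm$grid, "potential and class maps")
  stop_if_grid_mismatch(pm$grid, zones$template, "map and zone template")
  a <- cell_area_km2(pm$grid)
  v <- pm$grid$values
  means <- NULL; lvls <- NULL
  for (nm in names(zones$masks)) {
    mk <- zones$masks[[nm]] & !is.na(v)
    n <- sum(mk)
    means <- rbind(means, data.frame(
      zone = nm, epoch = pm$epoch, area_km2 = n * a,
      mean_inrpi = if (n) mean(v[mk]) else NA_real_))
    la <- level_areas(cm, mask = zones$masks[[nm]])
    prop <- if (sum(la) > 0) la / sum(la) else rep(NA_real_, cm$K)
    lvls <- rbind(lvls, data.frame(
      zone = nm, level = seq_len(cm$K), label = cm$labels,
      area_km2 = unname(la), proportion = unname(prop)))
  }
  rownames(means) <- rownames(lvls) <- NULL
  list(means = means, levels = lvls)
}

#' Per-level area change and growth rate between two epochs
#'
#' @param areas_t1,areas_t2 named per-level area vectors (same labels), e.g.
#'   from [level_areas()].
#' @return data.frame with `level`, `area_t1_km2`, `area_t2_km2`,
#'   `delta_km2`, `growth_pct` (100*(a2-a1)/a1; `NA` when a1 = 0).
#' @export
level_change <- function(areas_t1, areas_t2) {
  if (!setequal(names(areas_t1), names(areas_t2)))
    stop("level labels differ between epochs", call. = FALSE)
  lv <- names(areas_t1)
  a1 <- as.numeric(areas_t1[lv]); a2 <- as.numeric(areas_t2[lv])
  data.frame(
    level = lv, area_t1_km2 = a1, area_t2_km2 = a2, delta_km2 = a2 - a1,
    growth_pct = ifelse(a1 > 0, 100 * (a2 - a1) / a1, NA_real_))
}
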