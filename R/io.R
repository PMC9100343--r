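#' Read a single-band raster from an ESRI ASCII grid
#'
#' The on-disk format is the plain-text ESRI ASCII grid (`.asc`): a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows north to south. The projected CRS lives in
#' a sidecar `<file>.prj` text file; a missing sidecar is a hard error because
#' downstream distance and area computations assume projected meters.
#'
#' @param path path to the `.asc` file.
#' @return a [raster_grid()] with nodata cells set to `NA`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  prj <- paste0(path, ".prj")
  if (!file.exists(prj))
    stop("missing CRS sidecar for raster ", path,
         " (expected ", prj, ")", call. = FALSE)
  crs <- trimws(readLines(prj, n = 1L, warn = FALSE))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  for (k in 1:6) {
    kv <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("raster ", path, " is not single-band ", nr, "x", nc,
         ": got ", length(vals), " values", call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m, cellsize = hdr$cellsize, xmin = hdr$xllcorner,
              ymax = hdr$yllcorner + nr * hdr$cellsize, crs = crs)
}

#' Write a raster as an ESRI ASCII grid (+ CRS sidecar)
#'
#' @param grid a [raster_grid()].
#' @param path output `.asc` path; `<path>.prj` is written alongside.
#' @param nodata numeric sentinel used on disk for `NA` cells.
#' @param digits significant digits written (default keeps full double
#'   precision so a write/read round trip is value-identical).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, nodata = -9999, digits = 17) {
  stopifnot(is_raster_grid(grid))
  v <- grid$values
  if (any(v[!is.na(v)] == nodata))
    stop("nodata sentinel ", nodata, " collides with a data value",
         call. = FALSE)
  v[is.na(v)] <- nodata
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    paste("ncols", nc), paste("nrows", nr),
    paste("xllcorner", format(grid$xmin, digits = 17)),
    paste("yllcorner", format(grid$ymax - nr * grid$cellsize, digits = 17)),
    paste("cellsize", format(grid$cellsize, digits = 17)),
    paste("NODATA_value", nodata))
  body <- apply(v, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(grid$crs, paste0(path, ".prj"))
  invisible(path)
}

#' Read point/line/polygon features from GeoJSON
#'
#' Supports FeatureCollections of Point, MultiPoint, LineString and Polygon
#' (outer ring only) in projected coordinates. Returns a [feature_set()].
#'
#' @param path GeoJSON file.
#' @param name feature set name; defaults to the file stem.
#' @param crs CRS identifier to attach (GeoJSON itself is CRS-silent here).
#' @export
read_features <- function(path, name = NULL,
                          crs = "local-metric") {
  gj <- jsonlite::read_json(path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pts <- list(); lns <- list(); pls <- list()
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  for (f in feats) {
    g <- if (!is.null(f$geometry)) f$geometry else f
    cc <- g$coordinates
    mat <- function(coords)
      do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    switch(g$type,
      Point      = pts[[length(pts) + 1L]] <- c(cc[[1]], cc[[2]]),
      MultiPoint = for (p in cc) pts[[length(pts) + 1L]] <- c(p[[1]], p[[2]]),
      LineString = lns[[length(lns) + 1L]] <- mat(cc),
      Polygon    = pls[[length(pls) + 1L]] <- mat(cc[[1]]),
      stop("unsupported GeoJSON geometry: ", g$type, call. = FALSE))
  }
  feature_set(name,
              points = if (length(pts)) do.call(rbind, pts) else NULL,
              lines = lns, polygons = pls, crs = crs)
}

#' Write a feature set as GeoJSON
#' @param fs a [feature_set()].
#' @param path output path.
#' @export
write_features <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  feats <- list()
  add <- function(type, coords)
    feats[[length(feats) + 1L]] <<- list(
      type = "Feature", properties = list(name = fs$name),
      geometry = list(type = type, coordinates = coords))
  if (!is.null(fs$points))
    for (k in seq_len(nrow(fs$points))) add("Point", as.list(fs$points[k, ]))
  for (l in fs$lines)
    add("LineString", lapply(seq_len(nrow(l)), function(k) as.list(l[k, ])))
  for (p in fs$polygons)
    add("Polygon", list(lapply(seq_len(nrow(p)), function(k) as.list(p[k, ]))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an indicator weight table from CSV
#'
#' Expected columns: `code` plus any of `w_ahp`, `w_eem`, `w_combined`.
#' Returns a list of [weight_set()] objects, one per weight column present.
#'
#' @param path CSV file.
#' @param epoch optional epoch label attached to the sets.
#' @export
read_weight_table <- function(path, epoch = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"code" %in% names(df)) stop("weight table needs a 'code' column",
                                   call. = FALSE)
  kinds <- c(w_ahp = "ahp", w_eem = "eem", w_combined = "combined")
  out <- list()
  for (col in names(kinds)) {
    if (col %in% names(df)) {
      w <- stats::setNames(df[[col]], df$code)
      out[[kinds[[col]]]] <- weight_set(w, kind = kinds[[col]], epoch = epoch)
    }
  }
  if (!length(out)) stop("no weight columns (w_ahp/w_eem/w_combined) in ",
                         path, call. = FALSE)
  out
}

#' Write weight sets to CSV
#' @param sets named list with any of `ahp`, `eem`, `combined` weight sets
#'   (identical code sets).
#' @param path output CSV.
#' @export
write_weight_table <- function(sets, path) {
  codes <- names(sets[[1]]$weights)
  df <- data.frame(code = codes)
  map <- c(ahp = "w_ahp", eem = "w_eem", combined = "w_combined")
  for (k in names(sets))
    df[[map[[k]]]] <- unname(sets[[k]]$weights[codes])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a square judgment matrix from CSV (no header)
#' @param path CSV with n rows of n positive entries.
#' @export
read_judgment_matrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  judgment_matrix(m)
}

#' Read a YAML run configuration
#' @param path YAML file.
#' @export
read_config <- function(path) yaml::read_yaml(path)
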