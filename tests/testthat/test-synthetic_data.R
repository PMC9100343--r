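test_that("generation is bit-identical under one seed and differs across seeds", {
  b1 <- small_landscape(seed = 5)
  b2 <- small_landscape(seed = 5)
  expect_identical(b1$dem$values, b2$dem$values)
  expect_identical(b1$stacks[["2010"]]$layers$PRRI$grid$values,
                   b2$stacks[["2010"]]$layers$PRRI$grid$values)
  expect_identical(b1$landcover$grid$values, b2$landcover$grid$values)
  expect_identical(b1$features$lakes$points, b2$features$lakes$points)
  b3 <- small_landscape(seed = 6)
  expect_false(identical(b1$dem$values, b3$dem$values))
  # generating from the truth's echoed config round-trips
  b4 <- generate_landscape(b1$truth$config)
  expect_identical(b4$dem$values, b1$dem$values)
})

test_that("correlation length controls field autocorrelation", {
  lag1 <- function(f) {
    a <- as.vector(f[, -ncol(f)]); b <- as.vector(f[, -1])
    stats::cor(a, b)
  }
  set.seed(51)
  short <- replicate(25, lag1(recpot:::gaussian_field(50, 50, 1)))
  long <- replicate(25, lag1(recpot:::gaussian_field(50, 50, 20)))
  expect_gt(median(long), median(short))
  expect_gt(median(long), 0.8)
  expect_lt(median(short), 0.3)
})

test_that("a noiseless linear loading is recovered by OLS within 1e-6", {
  cfg <- landscape_config(nrow = 40, ncol = 40, epochs = 2000,
                          slope_pre = -0.3, slope_post = -0.3,
                          threshold_m = 3000, noise_sd = 0, field_sd = 0,
                          elev_noise_sd = 100,
                          indicator_ranges = list(TEM = c(0, 1)), seed = 8)
  b <- generate_landscape(cfg)
  x <- as.vector(b$dem$values) / 1000
  y <- as.vector(b$stacks[[1]]$layers$TEM$grid$values)
  expect_equal(unname(coef(lm(y ~ x))[2]), -0.3, tolerance = 1e-6)
  # negative-polarity layer carries the mirrored loading
  yn <- as.vector(b$stacks[[1]]$layers$PRRI$grid$values)
  r <- b$truth$ranges$PRRI
  expect_equal(unname(coef(lm(yn ~ x))[2]), 0.3 * (r[2] - r[1]),
               tolerance = 1e-4)
})

test_that("expected_truth echoes the planted parameters", {
  cfg <- landscape_config(threshold_m = 3000, drift_threshold_m = 25,
                          seed = 2)
  tr <- expected_truth(cfg)
  expect_equal(unname(tr$threshold_m), c(3000, 3025, 3050))
  expect_equal(tr$slope_post, -0.30)
  expect_equal(tr$minmax$TEM, c(-15, 10))
  expect_equal(unname(tr$polarity["DTL"]), "negative")
  b <- generate_landscape(landscape_config(nrow = 40, ncol = 40, seed = 2))
  expect_equal(b$truth$threshold_m, tr$threshold_m)
  # config validation
  expect_error(landscape_config(threshold_m = 9000), "inside elev_range")
  expect_error(landscape_config(pa_fraction = 1.2), "pa_fraction")
  expect_error(landscape_config(nrow = 10, ncol = 10, n_lakes = 200),
               "more point features")
})

test_that("generated structure matches the stated world", {
  b <- small_landscape(seed = 9)
  elev <- b$dem$values
  # DEM ramps SE -> NW: NW corner mean above SE corner mean
  expect_gt(mean(elev[1:15, 1:15]), mean(elev[46:60, 46:60]))
  # land-cover diversity declines with altitude
  h <- shdi_map(b$landcover, 3)$values
  lowcells <- elev < quantile(elev, 0.3)
  highcells <- elev > quantile(elev, 0.7)
  expect_gt(mean(h[lowcells]), mean(h[highcells]))
  # negative indicators rise with altitude, positive fall (post-threshold
  # decay dominates)
  expect_gt(cor(as.vector(elev),
                as.vector(b$stacks[[1]]$layers$PRRI$grid$values)), 0)
  expect_lt(cor(as.vector(elev),
                as.vector(b$stacks[[1]]$layers$TEM$grid$values)), 0)
  # zones: PA/NPA complement, halves partition
  zm <- b$zones$masks
  expect_true(all(xor(zm$PA, zm$NPA)))
  expect_true(all(xor(zm$SE_of_line, zm$NW_of_line)))
})

test_that("full pipeline on a generated landscape keeps its promises", {
  b <- small_landscape(seed = 10)
  pms <- small_pipeline(b)
  pm <- pms[[1]]
  v <- pm$grid$values
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  # protected-area placement bias lifts the PA mean above NPA
  s <- zone_summary(pm, classify(pm, "geometric_interval", K = 5), b$zones)
  m <- s$means
  expect_gt(m$mean_inrpi[m$zone == "PA"], m$mean_inrpi[m$zone == "NPA"])
  # the planted elevation threshold is visible to the segmented fit
  sp <- sample_points(pm, b$dem, 1000, seed = 77)
  fit <- fit_breakpoint(sp, step = 10)
  expect_true(fit$material)
  expect_lt(abs(fit$breakpoint_m - b$truth$threshold_m[["2000"]]), 300)
})

test_that("write_landscape produces a loadable bundle", {
  b <- generate_landscape(landscape_config(nrow = 20, ncol = 20,
                                           epochs = 2000, seed = 3))
  dir <- file.path(tempdir(), "bundle")
  write_landscape(b, dir)
  dem <- read_raster(file.path(dir, "dem.asc"))
  expect_equal(dem$values, b$dem$values)
  tem <- read_raster(file.path(dir, "TEM_2000.asc"))
  expect_equal(tem$values, b$stacks[[1]]$layers$TEM$grid$values)
  lakes <- read_features(file.path(dir, "lakes.geojson"))
  expect_equal(lakes$points, b$features$lakes$points)
  mm <- read.csv(file.path(dir, "minmax.csv"))
  expect_equal(mm$min[mm$code == "TEM"], b$truth$minmax$TEM[1])
})
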