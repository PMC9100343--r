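test_that("standardize hits its endpoints and linear interior", {
  g <- raster_grid(matrix(c(2, 4, 6), 1, 3), 1000)
  pos <- standardize(indicator_layer("TEM", g))
  expect_equal(as.vector(pos$values), c(0, 0.5, 1))
  neg <- standardize(indicator_layer("PRRI", g))
  expect_equal(as.vector(neg$values), c(1, 0.5, 0))  # min scores 1
  # supplied minmax clips out-of-range values
  clip <- standardize(indicator_layer("TEM", g), minmax = c(3, 5))
  expect_equal(as.vector(clip$values), c(0, 0.5, 1))
  expect_error(standardize(indicator_layer("TEM",
                                           raster_grid(matrix(7, 2, 2),
                                                       1000))),
               "constant")
  # ...but a supplied range rescues a constant layer
  const <- standardize(indicator_layer("TEM", raster_grid(matrix(7, 2, 2),
                                                          1000)),
                       minmax = c(0, 10))
  expect_true(all(const$values == 0.7))
})

test_that("compute_inrpi is the expected convex combination", {
  mm <- unit_minmax()
  # all standardized scores 1 -> INRPI 1 (positive at max, negative at min)
  st <- full_stack(function(code)
    matrix(if (registry_polarity_t(code) == "positive") 1 else 0, 4, 4))
  pm <- compute_inrpi(st, equal_weights(), minmax_policy = "global",
                      minmax = mm)
  expect_true(all(abs(pm$grid$values - 1) < 1e-12))

  # weight 1 on SHDI -> INRPI equals standardized SHDI
  set.seed(11)
  vals <- list()
  st <- full_stack(function(code) {
    vals[[code]] <<- matrix(runif(16), 4, 4)
    vals[[code]]
  })
  pm <- compute_inrpi(st, delta_weights("SHDI"), minmax_policy = "global",
                      minmax = mm)
  expect_equal(pm$grid$values, vals$SHDI, tolerance = 1e-12)

  # two-indicator toy cell: Xs (0.2, 0.8) with W (0.25, 0.75) -> 0.65
  w <- delta_weights("SHDI")$weights
  w["SHDI"] <- 0.25; w["RDLS"] <- 0.75
  w2 <- weight_set(w, "combined")
  st <- full_stack(function(code)
    matrix(switch(code, SHDI = 0.2, RDLS = 0.8, 0.5), 1, 1))
  pm <- compute_inrpi(st, w2, minmax_policy = "global", minmax = mm)
  expect_equal(pm$grid$values[1, 1], 0.65, tolerance = 1e-12)

  # missing indicator errors
  part <- indicator_stack(list(
    indicator_layer("TEM", raster_grid(matrix(1:4, 2, 2), 1000))))
  expect_error(compute_inrpi(part, equal_weights()), "missing indicators")
})

test_that("INRPI stays within the cellwise span of standardized scores", {
  set.seed(12)
  st <- full_stack(function(code) matrix(runif(64), 8, 8))
  mm <- unit_minmax()
  pm <- compute_inrpi(st, equal_weights(), minmax_policy = "global",
                      minmax = mm)
  xs <- sapply(st$layers, function(l)
    as.vector(standardize(l, minmax = c(0, 1))$values))
  expect_true(all(pm$grid$values >= matrix(apply(xs, 1, min), 8, 8) - 1e-12))
  expect_true(all(pm$grid$values <= matrix(apply(xs, 1, max), 8, 8) + 1e-12))
  expect_true(all(pm$grid$values >= 0 & pm$grid$values <= 1))
})

test_that("improving one indicator never lowers the index (monotonicity)", {
  set.seed(13)
  base_vals <- new.env()
  st <- full_stack(function(code) {
    v <- matrix(runif(25, 0.1, 0.9), 5, 5)
    assign(code, v, envir = base_vals)
    v
  })
  mm <- unit_minmax()
  w <- combine_weights(reference_weight_table()$ahp,
                       entropy_weights(st, minmax = mm))
  pm0 <- compute_inrpi(st, w, minmax_policy = "global", minmax = mm)
  for (code in c("SHDI", "PRRI", "DTL", "TEM")) {
    pol <- registry_polarity_t(code)
    v <- get(code, envir = base_vals)
    v[3, 3] <- v[3, 3] + if (pol == "positive") 0.05 else -0.05
    st2 <- full_stack(function(c2)
      if (c2 == code) v else get(c2, envir = base_vals))
    pm1 <- compute_inrpi(st2, w, minmax_policy = "global", minmax = mm)
    expect_gte(pm1$grid$values[3, 3], pm0$grid$values[3, 3])
  }
})

test_that("classify honors the fixed-break bin convention", {
  breaks <- c(0.31, 0.37, 0.46, 0.61)
  g <- raster_grid(matrix(c(0.25, 0.31, 0.37, 0.46, 0.50, 0.61, 0.80, 0.37,
                            0.369), 3, 3), 1000)
  cm <- classify(g, "fixed", K = 5, fixed_breaks = breaks)
  # left-closed: a value equal to an interior break joins the class above
  expect_equal(as.vector(cm$grid$values),
               c(1, 2, 3, 4, 4, 5, 5, 3, 2))
  expect_equal(cm$labels,
               c("very low", "low", "moderate", "high", "very high"))
  expect_error(classify(g, "fixed", K = 5, fixed_breaks = breaks[1:2]),
               "4 breakpoints")
  expect_warning(classify(g, "fixed", K = 2, fixed_breaks = 5), "outside")
})

test_that("geometric-interval breaks are monotone and hit equal widths on uniform data", {
  set.seed(14)
  g <- raster_grid(matrix(runif(10000), 100, 100), 1000)
  cm <- classify(g, "geometric_interval", K = 5)
  expect_false(is.unsorted(cm$breakpoints, strictly = TRUE))
  # oracle: on uniform data the within-class SS optimum is equal intervals
  lo <- min(g$values); hi <- max(g$values)
  equal <- lo + (hi - lo) * (1:4) / 5
  expect_equal(cm$breakpoints, equal, tolerance = 0.02)
  expect_lt(abs(cm$ratio - 1), 0.1)
  # conservation: level areas tally the full valid area
  expect_equal(sum(level_areas(cm)), sum(!is.na(g$values)) *
                 cell_area_km2(g))
})
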