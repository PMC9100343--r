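# shared in-code fixtures

# a full 15-layer stack where each layer's values come from `fn(code)`
# (a matrix) and standardization can be pinned with unit minmax
full_stack <- function(fn, epoch = "2000", cellsize = 1000) {
  layers <- lapply(indicator_registry()$code, function(code)
    indicator_layer(code, raster_grid(fn(code), cellsize)))
  indicator_stack(layers, epoch = epoch, complete = TRUE)
}

# minmax table pinning every indicator to [0, 1]
unit_minmax <- function() {
  codes <- indicator_registry()$code
  stats::setNames(lapply(codes, function(x) c(0, 1)), codes)
}

# equal combined weights over the 15 codes
equal_weights <- function() {
  codes <- indicator_registry()$code
  weight_set(stats::setNames(rep(1 / 15, 15), codes), kind = "combined")
}

# combined weights concentrated on one code
delta_weights <- function(code) {
  codes <- indicator_registry()$code
  w <- stats::setNames(rep(0, 15), codes)
  w[code] <- 1
  weight_set(w, kind = "combined")
}

# polarity lookup via the exported registry
registry_polarity_t <- function(code) {
  reg <- indicator_registry()
  reg$polarity[match(code, reg$code)]
}

# reciprocal matrix generated from a weight vector (perfectly consistent)
consistent_matrix <- function(w) outer(w, w, `/`)

# small default landscape for integration-style tests
small_landscape <- function(seed = 42, ...) {
  generate_landscape(landscape_config(nrow = 60, ncol = 60, seed = seed, ...))
}

# full small pipeline: entropy + reference AHP -> combined -> INRPI maps
small_pipeline <- function(bundle) {
  ref <- reference_weight_table()
  mm <- bundle$truth$minmax
  pms <- lapply(bundle$stacks, function(st) {
    eem <- entropy_weights(st, minmax = mm)
    compute_inrpi(st, combine_weights(ref$ahp, eem),
                  minmax_policy = "global", minmax = mm)
  })
  pms
}
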