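test_that("judgment matrix validation rejects malformed inputs", {
  expect_error(judgment_matrix(matrix(1, 2, 3)), "square")
  expect_error(judgment_matrix(matrix(1, 16, 16) + diag(0, 16)), "between 2 and 15")
  m <- matrix(c(1, 2, 3, 1), 2, 2)  # a21 != 1/a12
  expect_error(judgment_matrix(m), "reciprocal")
  m2 <- rbind(c(2, 2), c(0.5, 1))
  expect_error(judgment_matrix(m2), "diagonal")
})

test_that("ahp_weights solves hand-checkable matrices", {
  res <- ahp_weights(matrix(1, 3, 3))
  expect_equal(unname(res$weights$weights), rep(1 / 3, 3), tolerance = 1e-10)
  expect_equal(res$consistency$CR, 0, tolerance = 1e-9)

  m <- rbind(c(1, 2, 4), c(1 / 2, 1, 2), c(1 / 4, 1 / 2, 1))
  res <- ahp_weights(m)
  expect_equal(unname(res$weights$weights), c(4, 2, 1) / 7, tolerance = 1e-9)
  expect_equal(res$consistency$lambda_max, 3, tolerance = 1e-9)
  expect_equal(res$consistency$CR, 0, tolerance = 1e-9)
  expect_true(res$consistency$passes)
})

test_that("perturbed matrix consistency matches the eigen() oracle", {
  m <- rbind(c(1, 2, 9), c(1 / 2, 1, 2), c(1 / 9, 1 / 2, 1))
  res <- ahp_weights(m)
  # independent oracle: principal eigenvalue/vector via base eigen()
  ev <- eigen(m)
  lam <- Re(ev$values[1])
  w <- Re(ev$vectors[, 1]); w <- w / sum(w)
  expect_gt(res$consistency$CR, 0)
  expect_equal(res$consistency$lambda_max, lam, tolerance = 1e-8)
  expect_equal(res$consistency$CR, (lam - 3) / 2 / 0.58, tolerance = 1e-8)
  expect_equal(unname(res$weights$weights), w, tolerance = 1e-8)
})

test_that("consistent matrices of any order recover their weights exactly", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(3:9, 1)
    w <- runif(n, 0.2, 2); w <- w / sum(w)
    res <- ahp_weights(consistent_matrix(w))
    expect_equal(unname(res$weights$weights), w, tolerance = 1e-8)
    expect_equal(res$consistency$CR, 0, tolerance = 1e-9)
  }
})

test_that("entropy weights reproduce the closed-form two-indicator case", {
  # A constant (maximal entropy, zero weight), B one-hot (zero entropy)
  st <- indicator_stack(list(
    indicator_layer("TEM", raster_grid(matrix(c(1, 1, 1), 1, 3), 1000)),
    indicator_layer("PRE", raster_grid(matrix(c(0, 0, 1), 1, 3), 1000))),
    epoch = "toy")
  w <- entropy_weights(st, standardize = FALSE)
  E <- attr(w, "entropy")
  expect_equal(unname(E["TEM"]), 1)
  expect_equal(unname(E["PRE"]), 0)
  expect_equal(unname(w$weights[c("TEM", "PRE")]), c(0, 1))
})

test_that("entropy weights are invariant to cell relabeling", {
  set.seed(7)
  v1 <- matrix(runif(36), 6, 6); v2 <- matrix(runif(36)^2, 6, 6)
  mk <- function(a, b) indicator_stack(list(
    indicator_layer("TEM", raster_grid(a, 1000)),
    indicator_layer("PRE", raster_grid(b, 1000))))
  w <- entropy_weights(mk(v1, v2))
  perm <- sample(36)
  w2 <- entropy_weights(mk(matrix(v1[perm], 6, 6), matrix(v2[perm], 6, 6)))
  expect_equal(w$weights, w2$weights, tolerance = 1e-12)
})

test_that("degenerate entropy inputs error with the indicator named", {
  st <- indicator_stack(list(
    indicator_layer("TEM", raster_grid(matrix(2, 2, 2), 1000))))
  expect_error(entropy_weights(st), "TEM")
  # all layers uniform after standardization-free ingestion -> no signal
  st2 <- indicator_stack(list(
    indicator_layer("TEM", raster_grid(matrix(3, 2, 2), 1000)),
    indicator_layer("PRE", raster_grid(matrix(5, 2, 2), 1000))))
  expect_error(entropy_weights(st2, standardize = FALSE), "maximally entropic")
})

test_that("combine_weights reproduces the published fused table", {
  ref <- reference_weight_table()
  for (ep in c("2000", "2010", "2020")) {
    comb <- combine_weights(ref$ahp, ref[[ep]]$eem)
    printed <- ref[[ep]]$combined$weights
    expect_lt(max(abs(comb$weights[names(printed)] - printed)), 5e-4)
    expect_equal(sum(comb$weights), 1, tolerance = 1e-9)
  }
  # fixed point: identical inputs pass through
  same <- combine_weights(ref$ahp,
                          weight_set(ref$ahp$weights, "eem"))
  expect_equal(same$weights, ref$ahp$weights, tolerance = 1e-12)
  # code mismatch
  other <- weight_set(c(A = 0.5, B = 0.5), "eem")
  expect_error(combine_weights(ref$ahp, other), "different indicator codes")
})

test_that("weight_set enforces the sum-to-one and nonnegativity invariants", {
  expect_error(weight_set(c(a = 0.5, b = 0.4), "ahp"), "sum")
  expect_error(weight_set(c(a = 1.2, b = -0.2), "ahp"), "nonnegative")
  w <- weight_set(c(a = 2, b = 6), "eem", normalize = TRUE)
  expect_equal(unname(w$weights), c(0.25, 0.75))
})
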