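test_that("sigmoid hits its analytic anchor points with default parameters", {
  p <- scurve_params()
  # high-precision reference evaluations of the transform
  expect_equal(scurve_value(p$gamma, p), (p$alpha + p$beta) / 2,
               tolerance = 1e-12)
  expect_equal(scurve_value(0, p), 0.962797461094259, tolerance = 1e-12)
  expect_equal(scurve_value(1, p), 0.0021286121684709, tolerance = 1e-12)
})

test_that("midpoint and point symmetry hold for random parameter sets", {
  set.seed(101)
  for (i in 1:100) {
    # keep alpha/beta inside [0,1] so the post-sigmoid clamp stays inert
    ab <- sort(runif(2))
    p <- scurve_params(alpha = ab[2], beta = ab[1],
                       gamma = runif(1, 0.2, 0.8),
                       delta = runif(1, 0.02, 0.3))
    expect_equal(scurve_value(p$gamma, p), (p$alpha + p$beta) / 2,
                 tolerance = 1e-12)
    d <- runif(1, 0, 0.2)
    expect_equal(scurve_value(p$gamma + d, p) + scurve_value(p$gamma - d, p),
                 p$alpha + p$beta, tolerance = 1e-12)
  }
})

test_that("orientation follows the asymptote order", {
  r <- seq(0, 1, length.out = 1001)
  p <- scurve_params()                 # beta < alpha: decreasing
  expect_true(all(diff(scurve_value(r, p)) < 0))
  q <- scurve_invert(p)                # swapped: increasing
  expect_true(all(diff(scurve_value(r, q)) > 0))
})

test_that("parameter validation rejects degenerate sigmoids", {
  expect_error(scurve_params(delta = 0), "delta")
  expect_error(scurve_params(delta = -1), "delta")
  expect_error(scurve_params(alpha = 0.5, beta = 0.5), "differ")
})

test_that("global application is the elementwise map", {
  p <- scurve_params()
  u <- gray_image(matrix(p$gamma, 5, 5), "normalized")
  out <- scurve_global(u, p)
  expect_true(all(abs(pixels(out) - (p$alpha + p$beta) / 2) < 1e-12))

  m <- matrix(c(0, 0.25, 0.75, 1), 2, 2)
  out2 <- scurve_global(gray_image(m, "normalized"), p)
  expect_equal(pixels(out2), scurve_value(m, p))

  expect_error(scurve_global(rand_raw(4, 4, 1), p), "normalized")
})

test_that("the sigmoid map is not idempotent", {
  p <- scurve_params(alpha = 1, beta = 0)
  img <- gray_image(matrix(seq(0, 1, length.out = 16), 4, 4), "normalized")
  once <- scurve_global(img, p)
  twice <- scurve_global(once, p)
  expect_gt(max(abs(pixels(twice) - pixels(once))), 1e-3)
})

test_that("local application: constant tiles pass through unchanged", {
  u <- gray_image(matrix(0.37, 8, 8), "normalized")
  for (k in c(1, 2, 4)) {
    expect_equal(pixels(scurve_local(u, tiles = k, blend = FALSE)),
                 pixels(u))
    expect_equal(pixels(scurve_local(u, tiles = k, blend = TRUE)),
                 pixels(u))
  }
})

test_that("a single tile without blending degenerates to the global map", {
  # image spanning the full [0,1] range: per-tile renormalization is inert
  m <- matrix(seq(0, 1, length.out = 36), 6, 6)
  img <- gray_image(m, "normalized")
  local <- scurve_local(img, tiles = 1, blend = FALSE)
  expect_equal(pixels(local), pixels(scurve_global(img)), tolerance = 1e-12)
  # and with renormalization off the equivalence needs no range assumption
  m2 <- matrix(seq(0.2, 0.7, length.out = 36), 6, 6)
  img2 <- gray_image(m2, "normalized")
  local2 <- scurve_local(img2, tiles = 1, blend = FALSE, renormalize = FALSE)
  expect_equal(pixels(local2), pixels(scurve_global(img2)), tolerance = 1e-12)
})

test_that("unblended tiling matches the per-tile brute-force chain", {
  p <- scurve_params()
  chk <- matrix(0.2, 4, 4); chk[cbind(c(1, 2, 3, 4), c(2, 1, 4, 3))] <- 0.8
  got <- scurve_local(gray_image(chk, "normalized"), p, tiles = 2,
                      blend = FALSE)
  expect_equal(pixels(got), scurve_local_brute(chk, p, 2), tolerance = 1e-12)

  set.seed(7)
  m <- matrix(runif(144), 12, 12)
  for (k in c(2, 3, 4)) {
    got <- scurve_local(gray_image(m, "normalized"), p, tiles = k,
                        blend = FALSE)
    expect_equal(pixels(got), scurve_local_brute(m, p, k), tolerance = 1e-12)
  }
})

test_that("blending leaves no seams on a smooth ramp", {
  ramp <- matrix(rep(seq(0, 1, length.out = 64), each = 64), 64, 64,
                 byrow = TRUE)
  img <- gray_image(ramp, "normalized")
  out <- pixels(scurve_local(img, tiles = 4, blend = TRUE))
  grad <- abs(out[, -1] - out[, -64])
  col_tile <- ceiling(seq_len(64) / 64 * 4)
  boundary <- which(diff(col_tile) != 0)   # gap straddling two tiles
  expect_lte(max(grad[, boundary]), max(grad[, -boundary]))
})

test_that("every application mode stays inside [0,1]", {
  set.seed(33)
  img <- gray_image(matrix(runif(400), 20, 20), "normalized")
  for (p in list(scurve_params(), scurve_params(1.4, -0.2, 0.5, 0.05))) {
    for (out in list(scurve_global(img, p),
                     scurve_local(img, p, tiles = 4, blend = TRUE),
                     scurve_local(img, p, tiles = 4, blend = FALSE))) {
      expect_gte(min(pixels(out)), 0)
      expect_lte(max(pixels(out)), 1)
    }
  }
})

test_that("an oversized tile grid is rejected", {
  img <- gray_image(matrix(runif(16), 4, 4), "normalized")
  expect_error(scurve_local(img, tiles = 5), "does not fit")
})
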