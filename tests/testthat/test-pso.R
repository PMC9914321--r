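test_that("velocity update follows the canonical rule", {
  cfg <- pso_config(w = 1, c1 = 1e-9, c2 = 1e-9)   # inertia only
  v <- pso_update_velocity(0.25, 0.5, 0.9, 0.1, cfg, v_max = 10,
                           r1 = 0, r2 = 0)
  expect_equal(v, 0.25)

  # attraction terms vanish when x sits at both bests
  cfg <- pso_config(w = 0.7)
  v <- pso_update_velocity(0.3, 0.5, 0.5, 0.5, cfg, v_max = 10)
  expect_equal(v, 0.7 * 0.3)

  # hand arithmetic: 0.5*0.2 + 1*0.5*(0.4-0) + 1*0.5*(1-0) = 0.8
  cfg <- pso_config(w = 0.5, c1 = 1, c2 = 1)
  v <- pso_update_velocity(0.2, 0, 0.4, 1, cfg, v_max = 10,
                           r1 = 0.5, r2 = 0.5)
  expect_equal(v, 0.8)
  # and the cap clips it
  v <- pso_update_velocity(0.2, 0, 0.4, 1, cfg, v_max = 0.3,
                           r1 = 0.5, r2 = 0.5)
  expect_equal(v, 0.3)

  expect_error(pso_update_velocity(c(0, 0), 0.5, 0.5, 0.5, cfg, 1),
               "dimension")
})

test_that("position update is a unit step with absorbing walls", {
  upd <- pso_update_position(0.5, 0.1, 0, 1)
  expect_equal(upd$position, 0.6)
  expect_equal(upd$velocity, 0.1)

  upd <- pso_update_position(1, 0.2, 0, 1)      # pushes past the wall
  expect_equal(upd$position, 1)
  expect_equal(upd$velocity, 0)

  upd <- pso_update_position(c(0.5, 0.5), c(0, 0), c(0, 0), c(1, 1))
  expect_equal(upd$position, c(0.5, 0.5))
})

test_that("the swarm recovers the optimum of a quadratic", {
  hits <- 0L
  for (seed in 1:10) {
    res <- pso_maximize(function(x) -(x - 0.3)^2, 0, 1,
                        pso_config(swarm_size = 30, iterations = 50,
                                   seed = seed))
    if (abs(res$best_position - 0.3) < 1e-3) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("gbest trace is non-decreasing and runs are seed-reproducible", {
  obj <- function(x) sin(7 * x[1]) * cos(3 * x[2])
  res1 <- pso_maximize(obj, c(0, 0), c(1, 1),
                       pso_config(iterations = 20, seed = 42))
  res2 <- pso_maximize(obj, c(0, 0), c(1, 1),
                       pso_config(iterations = 20, seed = 42))
  expect_identical(res1, res2)
  expect_true(all(diff(res1$gbest_trace) >= 0))
  expect_equal(res1$best_fitness, res1$gbest_trace[length(res1$gbest_trace)])
  expect_length(res1$gbest_trace, 21L)
})

test_that("every evaluated position stays inside the bounds", {
  seen <- list()
  obj <- function(x) { seen[[length(seen) + 1L]] <<- x; -sum(x^2) }
  pso_maximize(obj, c(-1, 2), c(1, 5),
               pso_config(swarm_size = 10, iterations = 15, seed = 3))
  m <- do.call(rbind, seen)
  expect_true(all(m[, 1] >= -1 & m[, 1] <= 1))
  expect_true(all(m[, 2] >= 2 & m[, 2] <= 5))
})

test_that("degenerate bounds and bad configs are rejected", {
  expect_error(pso_maximize(identity, 1, 1, pso_config()), "bounds")
  expect_error(pso_config(swarm_size = 1), "swarm_size")
  expect_error(pso_config(iterations = 0), "iterations")
})

test_that("EME fitness equals recomputation through the two modules", {
  ph <- generate_phantom(phantom_spec(height = 32, width = 32, seed = 21))
  norm <- normalize(ph$image)
  cand <- c(alpha = 0.9642, beta = 8.594e-4)
  f <- scurve_fitness(norm, cand)
  enh <- scurve_local(norm, scurve_params(), tiles = 8, blend = TRUE)
  expect_equal(f, eme(denormalize(enh)), tolerance = 1e-12)

  # a constant image scores zero for every candidate
  flat <- gray_image(matrix(0.5, 16, 16), "normalized")
  expect_equal(scurve_fitness(flat, cand), 0)
  expect_equal(scurve_fitness(flat, c(alpha = 0.7, beta = 0.2)), 0)
})

test_that("elitist initialization keeps the optimum at or above the fixed point", {
  for (seed in c(2, 9)) {
    ph <- generate_phantom(phantom_spec(height = 32, width = 32, seed = seed,
                                        preset = "low_contrast"))
    norm <- normalize(ph$image)
    fixed <- scurve_fitness(norm, c(alpha = 0.9642, beta = 8.594e-4))
    res <- optimize_scurve(norm, cfg = pso_config(seed = seed))
    expect_gte(res$best_fitness, fixed)
    expect_s3_class(res$best_params, "scurve_params")
    expect_true(all(diff(res$gbest_trace) >= 0))
  }
})

test_that("widened tuning over all four parameters is available", {
  ph <- generate_phantom(phantom_spec(height = 24, width = 24, seed = 4))
  norm <- normalize(ph$image)
  res <- optimize_scurve(
    norm, cfg = pso_config(swarm_size = 10, iterations = 3, seed = 1),
    bounds = list(alpha = c(0.5, 1), beta = c(0, 0.5),
                  gamma = c(0.2, 0.8), delta = c(0.02, 0.3))
  )
  expect_named(res$best_position, c("alpha", "beta", "gamma", "delta"))
  expect_true(res$best_params$gamma >= 0.2 && res$best_params$gamma <= 0.8)
})
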