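test_that("a constant image has zero detail and the expected haar LL", {
  S <- dwt2(matrix(5, 6, 6), "haar")
  expect_true(all(abs(S$lh[[1]]) < 1e-12))
  expect_true(all(abs(S$hl[[1]]) < 1e-12))
  expect_true(all(abs(S$hh[[1]]) < 1e-12))

  # 2x2 butterfly with orthonormal scaling: ll = (a+b+c+d)/2
  S2 <- dwt2(matrix(c(1, 3, 2, 4), 2, 2), "haar")
  expect_equal(S2$ll[1, 1], (1 + 2 + 3 + 4) / 2, tolerance = 1e-12)
  expect_equal(dim(S2$ll), c(1L, 1L))
})

test_that("level-1 sub-bands measure ceil(side/2)", {
  S <- dwt2(matrix(0, 5, 7), "haar")
  expect_equal(dim(S$ll), c(3L, 4L))
  expect_equal(dim(S$hh[[1]]), c(3L, 4L))
})

test_that("forward/inverse transform is a perfect reconstruction pair", {
  set.seed(14)
  for (wv in c("haar", "db2", "db4", "sym4")) {
    for (sz in list(c(8, 8), c(5, 7), c(33, 31), c(64, 64))) {
      x <- matrix(runif(sz[1] * sz[2], 0, 255), sz[1], sz[2])
      r <- idwt_reconstruct(dwt2(x, wv))
      expect_equal(dim(r), dim(x))
      expect_lt(max(abs(r - x)), 1e-8)
    }
  }
  # deeper decompositions reconstruct too
  x <- matrix(runif(37 * 41, 0, 255), 37, 41)
  expect_lt(max(abs(idwt_reconstruct(dwt2(x, "db2", level = 3)) - x)), 1e-8)
})

test_that("all-zero sub-bands reconstruct to an all-zero image", {
  S <- dwt2(matrix(runif(64), 8, 8), "db2")
  S$ll[] <- 0; S$lh[[1]][] <- 0; S$hl[[1]][] <- 0; S$hh[[1]][] <- 0
  expect_true(all(abs(idwt_reconstruct(S)) < 1e-12))
})

test_that("unknown wavelets and undersized images are rejected", {
  expect_error(dwt2(matrix(0, 8, 8), "morlet"), "unknown wavelet")
  expect_error(dwt2(matrix(0, 1, 8), "haar"), "2x2")
})

test_that("maximum fusion equals the elementwise brute force in both modes", {
  set.seed(6)
  A <- dwt2(matrix(runif(100, 0, 255), 10, 10), "haar")
  B <- dwt2(matrix(runif(100, 0, 255), 10, 10), "haar")

  Fp <- fuse_max(A, B, "plain_max")
  expect_equal(Fp$ll, pmax(A$ll, B$ll))
  for (band in c("lh", "hl", "hh")) {
    a <- A[[band]][[1]]; b <- B[[band]][[1]]
    brute <- matrix(mapply(max, a, b), nrow(a), ncol(a))
    expect_equal(Fp[[band]][[1]], brute)
    expect_true(all(Fp[[band]][[1]] >= a) && all(Fp[[band]][[1]] >= b))
  }

  Fa <- fuse_max(A, B, "abs_max")
  expect_equal(Fa$ll, pmax(A$ll, B$ll))   # approximate band: plain max
  for (band in c("lh", "hl", "hh")) {
    a <- A[[band]][[1]]; b <- B[[band]][[1]]
    brute <- matrix(mapply(function(u, v) if (abs(u) >= abs(v)) u else v,
                           a, b), nrow(a), ncol(a))
    expect_equal(Fa[[band]][[1]], brute)
  }
})

test_that("fusion is idempotent and commutes under argument swap", {
  set.seed(16)
  A <- dwt2(matrix(runif(80, 0, 255), 8, 10), "db2")
  B <- dwt2(matrix(runif(80, 0, 255), 8, 10), "db2")
  expect_equal(fuse_max(A, A), A)
  expect_equal(fuse_max(A, B), fuse_max(B, A))
  expect_error(fuse_max(A, dwt2(matrix(0, 8, 10), "haar")),
               "different wavelets")
  expect_error(fuse_max(A, dwt2(matrix(0, 6, 6), "db2")), "shapes")
})

test_that("image-level fusion keeps shape and fixes its fixed point", {
  for (sz in list(c(16, 16), c(15, 17))) {
    img <- rand_raw(sz[1], sz[2], sum(sz))
    fused <- fuse_images(img, img)
    expect_equal(dim(fused), dim(img))
    expect_lt(max(abs(pixels(fused) - pixels(img))), 1e-6)
  }
})

test_that("plain-max fusion does not darken below both inputs on phantoms", {
  for (seed in 1:3) {
    a <- generate_phantom(phantom_spec(height = 32, width = 32,
                                       seed = seed))$image
    b <- generate_phantom(phantom_spec(height = 32, width = 32,
                                       seed = seed + 10,
                                       background_level = 140))$image
    fused <- fuse_images(a, b)
    expect_gte(mean(pixels(fused)),
               min(mean(pixels(a)), mean(pixels(b))) - 1e-9)
  }
})

test_that("fusing mismatched images fails cleanly", {
  expect_error(fuse_images(rand_raw(8, 8, 1), rand_raw(8, 9, 2)), "shape")
  expect_error(fuse_images(rand_raw(8, 8, 1), normalize(rand_raw(8, 8, 2))),
               "raw")
})
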