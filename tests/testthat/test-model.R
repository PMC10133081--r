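test_that("generator preserves shape, bounds its range, and is seeded", {
  with_test_seed(1, G <- build_generator(4, 2))
  x <- with_test_seed(2, matrix(runif(64 * 64, -1, 1), 64, 64))
  y <- generator_forward(G, x)
  expect_identical(dim(y), dim(x))
  expect_true(all(y >= -1 & y <= 1))
  expect_error(generator_forward(G, matrix(0, 66, 66)), "divisible by 4")
  with_test_seed(1, G2 <- build_generator(4, 2))
  expect_identical(generator_forward(G2, x), y)
})

test_that("discriminator maps slices to patch score maps (H / 16)", {
  with_test_seed(3, D <- build_discriminator(4))
  s64 <- discriminator_forward(D, matrix(0.1, 64, 64))
  expect_identical(dim(s64), c(4L, 4L))
  s128 <- discriminator_forward(D, matrix(0.1, 128, 128))
  expect_identical(dim(s128), c(8L, 8L))
  expect_true(all(is.finite(s64)))
  expect_error(discriminator_forward(D, matrix(0, 8, 8)), "divisible by 16")
})

test_that("registration network emits a same-shape field, identity at init", {
  with_test_seed(4, R <- build_regnet(4))
  g <- matrix(runif(64 * 64, -1, 1), 64, 64)
  y <- matrix(runif(64 * 64, -1, 1), 64, 64)
  f <- regnet_forward(R, g, y)
  expect_identical(dim(f), c(64L, 64L, 2L))
  expect_true(all(f == 0))       # zero-initialized final layer
  expect_error(regnet_forward(R, g, matrix(0, 32, 32)), "different shapes")
  with_test_seed(4, R2 <- build_regnet(4))
  expect_identical(regnet_forward(R2, g, y), f)
})

test_that("warp: zero field is the identity, integer shifts are exact", {
  img <- with_test_seed(5, matrix(rnorm(100), 10, 10))
  zf <- array(0, c(10, 10, 2))
  expect_identical(warp(img, zf), img)

  one_col <- zf
  one_col[, , 2] <- 1
  bright <- matrix(0, 10, 10)
  bright[5, 6] <- 1
  w <- warp(bright, one_col)
  expect_equal(w[5, 5], 1)        # pixel moves one column left in output
  expect_equal(sum(w[, 1:9]), sum(bright[, 2:10]))

  half <- zf
  half[, , 2] <- 0.5
  ramp <- matrix(rep(c(0, 1), each = 10), 10, 2)
  ramp_full <- cbind(ramp, matrix(1, 10, 8))
  wh <- warp(ramp_full, half)
  expect_equal(wh[, 1], rep(0.5, 10))   # bilinear midpoint average
})

test_that("warp is linear in the image and approximately invertible", {
  with_test_seed(6, {
    i1 <- matrix(rnorm(64 * 64), 64, 64)
    i2 <- matrix(rnorm(64 * 64), 64, 64)
  })
  f <- smooth_field_2d(64, 64, mag = 2, seed = 2)
  lhs <- warp(0.3 * i1 + 1.7 * i2, f)
  rhs <- 0.3 * warp(i1, f) + 1.7 * warp(i2, f)
  expect_lt(max(abs(lhs - rhs)), 1e-6)

  p <- tiny_phantom()
  img <- clip_normalize(p$ct)$data[8, , ]
  rt <- warp(warp(img, f), -f)
  rng <- diff(range(img))
  expect_lt(mean(abs(rt - img)) / rng, 0.05)
})

test_that("checkpoints round-trip and reject corrupt files", {
  with_test_seed(1, {
    G <- build_generator(2, 1)
    D <- build_discriminator(2)
    R <- build_regnet(2)
  })
  cfg <- train_config(ngf = 2, ndf = 2, nrf = 2)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(f, G, D, R, cfg)
  ck <- load_checkpoint(f)
  x <- matrix(runif(64 * 64, -1, 1), 64, 64)
  expect_identical(generator_forward(ck$G, x), generator_forward(G, x))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(version = "other"), bad)
  expect_error(load_checkpoint(bad), "version")
})
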