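test_that("identity generator reduces translation to the clip window", {
  p <- tiny_phantom()
  cb <- degrade_to_cbct(p$ct, artifact_spec(seed = 6))
  ck <- list(G = identity_generator())
  sct <- translate_volume(ck, cb)
  expect_equal(sct$data, pmin(pmax(cb$data, -1000), 2000), tolerance = 1e-9)
  expect_identical(sct$spacing, cb$spacing)
  expect_identical(sct$origin, cb$origin)
})

test_that("slice order is preserved (watermark check)", {
  p <- tiny_phantom()
  vol <- p$ct
  vol$data[11, 30:34, 30:34] <- 1234   # watermark one slice
  sct <- translate_volume(list(G = identity_generator()), vol)
  marked <- which(apply(sct$data, 1, function(s) any(abs(s - 1234) < 1)))
  expect_identical(marked, 11L)
})

test_that("translation output is HU-bounded, shape-stable, deterministic", {
  with_test_seed(5, G <- build_generator(2, 1))
  ck <- list(G = G)
  sl <- matrix(runif(64 * 64, -1200, 3500), 64, 64)
  out1 <- translate_slice(ck, sl)
  out2 <- translate_slice(ck, sl)
  expect_identical(out1, out2)
  expect_identical(dim(out1), c(64L, 64L))
  expect_true(all(out1 >= -1000 & out1 <= 2000))
  # non-multiple-of-4 dims go through internal padding
  odd <- matrix(runif(30 * 50, -500, 500), 30, 50)
  out3 <- translate_slice(ck, odd)
  expect_identical(dim(out3), c(30L, 50L))

  p <- tiny_phantom()
  v1 <- translate_volume(ck, p$ct)
  v2 <- translate_volume(ck, p$ct)
  expect_identical(v1$data, v2$data)
})
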