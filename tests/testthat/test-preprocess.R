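test_that("clip-normalize maps the clip window onto [-1, 1]", {
  v <- image_volume(array(c(-1000, 2000, 500, 3000, -2000, 0),
                          c(1, 2, 3)), frame = "cbct")
  nv <- clip_normalize(v)
  expect_equal(as.numeric(nv$data), c(-1, 1, 0, 1, -1, -1 / 3))
  # idempotent on already-clipped input, monotone
  nv2 <- clip_normalize(denormalize(nv))
  expect_equal(nv2$data, nv$data, tolerance = 1e-12)
  x <- sort(runif(50, -1500, 2500))
  y <- clip_normalize(image_volume(array(x, c(1, 1, 50))))$data
  expect_true(all(diff(as.numeric(y)) >= 0))
})

test_that("denormalize inverts the mapping and rejects out-of-range input", {
  expect_equal(denormalize(array(0, c(1, 1, 1)))$data[1], 500)
  expect_equal(denormalize(array(-1, c(1, 1, 1)))$data[1], -1000)
  expect_error(denormalize(array(1.5, c(1, 1, 1))), "\\[-1, 1\\]")
  with_test_seed(4, {
    v <- array(runif(60, -1, 1), c(3, 4, 5))
    round_trip <- clip_normalize(denormalize(v))$data
    expect_lt(max(abs(round_trip - v)), 1e-9)
  })
})

test_that("crop_resize preserves central blocks and pads with air", {
  v <- image_volume(array(as.numeric(seq_len(4 * 64 * 64)), c(4, 64, 64)),
                    spacing = c(4, 4, 4))
  expect_identical(crop_resize(v, dim(v$data))$data, v$data)
  cr <- crop_resize(v, c(4, 32, 32))
  expect_identical(cr$data, v$data[, 17:48, 17:48])
  pd <- crop_resize(v, c(4, 96, 96))
  expect_identical(pd$data[, 17:80, 17:80], v$data)
  expect_true(all(pd$data[, 1:16, ] == -1000))
})

test_that("rigid registration recovers synthetic translations and rotations", {
  p <- tiny_phantom()
  mov <- p$ct
  mov$origin <- mov$origin + c(0, 8, 0)   # known 8 mm shift along rows
  rr <- rigid_register(mov, p$ct)
  expect_lt(abs(abs(rr$params[["t_row"]]) - 8), 4)   # within one voxel
  expect_lt(max(abs(rr$params[c("t_slice", "t_col")])), 4)

  ri <- rigid_register(p$ct, p$ct)
  expect_lt(max(abs(ri$params[1:3])), 1)
  expect_lt(max(abs(ri$params[4:6])), 1)

  # known 5-degree in-plane rotation, built with the package's resampler
  ns <- asNamespace("regganct")
  rot <- ns$rigid_resample(p$ct, p$ct, c(0, 0, 0, 5, 0, 0))
  rr2 <- rigid_register(rot, p$ct)
  expect_lt(abs(abs(rr2$params[["rot_slice"]]) - 5), 1)

  far <- p$ct
  far$origin <- far$origin + c(0, 0, 1e4)
  expect_error(rigid_register(far, p$ct), "overlap")
})

test_that("deformable registration improves alignment on phantom pairs", {
  p <- tiny_phantom()
  day <- make_day_anatomy(p$ct, p$rois, deform_spec(magnitude = 3, seed = 9))
  cb <- degrade_to_cbct(day$ct, artifact_spec(seed = 4),
                        lung_mask = day$rois$lung_total)
  dr <- deformable_register(p$ct, cb)
  mae_before <- mean(abs(p$ct$data - day$ct$data))
  mae_after <- mean(abs(dr$dct$data - day$ct$data))
  expect_lt(mae_after, mae_before)
  # body-contour alignment (automated checkerboard surrogate)
  d_dct <- dice(body_mask(dr$dct), body_mask(cb))
  d_pl <- dice(body_mask(p$ct), body_mask(cb))
  expect_gte(d_dct, d_pl)

  # identity pair: dCT no worse, estimated field stays small
  dri <- deformable_register(p$ct, p$ct)
  expect_lte(mean(abs(dri$dct$data - p$ct$data)), 1e-6)
  med <- median(sqrt(dri$field[, , , 1]^2 + dri$field[, , , 2]^2 +
                       dri$field[, , , 3]^2))
  expect_lt(med, 0.5)
})
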