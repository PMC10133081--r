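test_that("phantom tissue classes carry their exact HU values", {
  p <- tiny_phantom()
  spec <- phantom_spec(seed = 7)
  expect_true(all(p$ct$data[p$rois$lung_total] == spec$hu[["lung"]]))
  expect_true(all(p$ct$data[p$rois$cord] == spec$hu[["cord"]]))
  expect_true(all(p$ct$data[p$rois$bone] == spec$hu[["bone"]]))
  expect_true(all(p$ct$data[!p$rois$body] == spec$hu[["air"]]))
})

test_that("phantom mask algebra holds", {
  p <- tiny_phantom()
  r <- p$rois
  expect_identical(r$lung_total, r$lung_left | r$lung_right)
  expect_false(any(r$ctv & !r$ptv))         # CTV subset of PTV
  for (nm in names(r))
    expect_false(any(r[[nm]] & !r$body), info = nm)
  expect_gt(sum(r$ptv), sum(r$ctv))
})

test_that("degenerate geometry errors name the organ", {
  expect_error(phantom_spec(ctv_radius = 0), "CTV")
  expect_error(make_phantom(phantom_spec(body_semi = c(400, 120))), "body")
  expect_error(make_phantom(phantom_spec(heart_center = c(0, 150, 0),
                                         jitter_mm = 0)), "heart")
})

test_that("body histogram shows the lung peak near -900 HU", {
  p <- tiny_phantom()
  h <- hu_histogram(p$ct, p$rois$body)
  # modal HU inside the lung mask is the spec's lung HU
  hl <- hu_histogram(p$ct, p$rois$lung_total)
  expect_lt(abs(hl$center[which.max(hl$count)] - (-900)), 10)
  # and the sub-soft-tissue range of the body histogram peaks there too
  low <- h[h$center < -400, ]
  peak <- low$center[which.max(low$count)]
  expect_lt(abs(peak - (-900)), 10)
  expect_gt(max(low$count), 0.8 * sum(p$rois$lung_total))
})

test_that("day anatomy: zero magnitude is the identity", {
  p <- tiny_phantom()
  day <- make_day_anatomy(p$ct, p$rois, deform_spec(magnitude = 0, seed = 5))
  expect_identical(day$ct$data, p$ct$data)
  expect_true(all(day$field == 0))
})

test_that("uniform integer shift warps exactly (degenerate smoothness)", {
  p <- tiny_phantom()
  d <- dim(p$ct$data)
  field <- array(0, c(d, 3))
  field[, , , 2] <- 2              # pull from 2 rows ahead
  ns <- asNamespace("regganct")
  shifted <- ns$warp3d_cpp(p$ct$data, field, as.integer(d), 0L)
  # direct array-shift oracle (border rows clamp)
  expect_equal(shifted[, 1:(d[2] - 2), ], p$ct$data[, 3:d[2], ],
               tolerance = 1e-12)
})

test_that("emitted deformation respects the magnitude bound", {
  p <- tiny_phantom()
  for (seed in c(3, 8)) {
    day <- make_day_anatomy(p$ct, p$rois, deform_spec(magnitude = 2.5,
                                                      seed = seed))
    nrm <- sqrt(day$field[, , , 1]^2 + day$field[, , , 2]^2 +
                  day$field[, , , 3]^2)
    expect_lte(max(nrm), 2.5 + 1e-12)
  }
})

test_that("zero-amplitude degradation is the identity", {
  p <- tiny_phantom()
  a <- artifact_spec(shading_amp = 0, streak_amp = 0, lung_offset = 0,
                     noise_sd = 0, seed = 5)
  cb <- degrade_to_cbct(p$ct, a)
  expect_equal(cb$data, p$ct$data, tolerance = 1e-12)
})

test_that("pure lung offset raises lung mean by its amount", {
  p <- tiny_phantom()
  a <- artifact_spec(shading_amp = 0, streak_amp = 0, lung_offset = 150,
                     noise_sd = 0, seed = 5)
  cb <- degrade_to_cbct(p$ct, a, lung_mask = p$rois$lung_total)
  lung_rise <- mean(cb$data[p$rois$lung_total]) -
    mean(p$ct$data[p$rois$lung_total])
  expect_lt(abs(lung_rise - 150), 1)
  soft <- p$rois$body & !p$rois$lung_total
  expect_equal(cb$data[soft], p$ct$data[soft], tolerance = 1e-12)
})

test_that("CBCT error grows with each artifact amplitude in isolation", {
  p <- tiny_phantom()
  day <- make_day_anatomy(p$ct, p$rois, deform_spec(seed = 3))
  body <- day$rois$body
  mae_for <- function(...) {
    a <- artifact_spec(shading_amp = 0, streak_amp = 0, lung_offset = 0,
                       noise_sd = 0, seed = 5)
    a[names(list(...))] <- list(...)
    cb <- degrade_to_cbct(day$ct, a, lung_mask = day$rois$lung_total)
    mean(abs(cb$data[body] - day$ct$data[body]))
  }
  for (knob in c("shading_amp", "streak_amp", "noise_sd")) {
    mae <- vapply(c(0, 20, 40), function(amp)
      do.call(mae_for, stats::setNames(list(amp), knob)), numeric(1))
    expect_true(all(diff(mae) > 0), info = knob)
  }
  # the default (all artifacts on) CBCT has substantial error
  cb <- degrade_to_cbct(day$ct, artifact_spec(seed = 5),
                        lung_mask = day$rois$lung_total)
  expect_gt(mean(abs(cb$data[body] - day$ct$data[body])), 0)
})

test_that("toy dose is scaled to the prescription and follows the PTV", {
  p <- tiny_phantom()
  dose <- make_dose(p$rois, 50.4, 5, spacing = p$ct$spacing)
  expect_lt(abs(median(dose$data[p$rois$ptv]) - 50.4), 1e-6)
  expect_true(all(dose$data >= 0))
  expect_error(make_dose(p$rois, 50.4, 0), "n_beams")
  empty <- structure_set(list(ptv = array(FALSE, dim(p$ct$data)),
                              body = p$rois$body))
  expect_error(make_dose(empty, 50.4, 5), "PTV")

  # argmax follows the PTV centroid
  spec2 <- phantom_spec(seed = 7, eso_center = c(-20, -30), jitter_mm = 0)
  spec1 <- phantom_spec(seed = 7, jitter_mm = 0)
  p1 <- make_phantom(spec1)
  p2 <- make_phantom(spec2)
  d1 <- make_dose(p1$rois, 50.4, 5, spacing = spec1$spacing)
  d2 <- make_dose(p2$rois, 50.4, 5, spacing = spec2$spacing)
  am1 <- which(d1$data == max(d1$data), arr.ind = TRUE)[1, ]
  am2 <- which(d2$data == max(d2$data), arr.ind = TRUE)[1, ]
  c1 <- colMeans(which(p1$rois$ptv, arr.ind = TRUE))
  c2 <- colMeans(which(p2$rois$ptv, arr.ind = TRUE))
  # dose peak moves in the same direction as the centroid
  expect_gt(sum((am1 - am2) * (c1 - c2)), 0)
})

test_that("dataset generation is deterministic and self-consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- make_dataset(2, 1, d1, seed = 11)
  m2 <- make_dataset(2, 1, d2, seed = 11)
  expect_equal(nrow(m1), 3)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  s1 <- tools::md5sum(file.path(d1, f1))
  s2 <- tools::md5sum(file.path(d2, f1))
  expect_true(all(unname(s1) == unname(s2)))
  # every emitted CBCT differs from its day CT
  for (pt in sprintf("pt%03d", 1:3)) {
    cb <- read_volume(file.path(d1, pt, "cbct.nii.gz"))
    day <- read_volume(file.path(d1, pt, "day.nii.gz"))
    expect_gt(mean(abs(cb$data - day$data)), 0)
    rois <- decode_rois(read_volume(file.path(d1, pt, "rois.nii.gz"))$data)
    expect_identical(rois$lung_total, rois$lung_left | rois$lung_right)
    expect_false(any(rois$ctv & !rois$ptv))
  }
})
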