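vol_of <- function(arr, spacing = c(4, 4, 4)) {
  image_volume(arr, spacing = spacing, frame = "dose")
}

test_that("gamma closed forms: identical and uniformly offset doses", {
  u <- array(50, c(6, 8, 8))
  same <- gamma_map(vol_of(u), vol_of(u))
  expect_true(all(same$gamma == 0))
  expect_equal(same$pass_rate, 100)

  two_pct <- gamma_map(vol_of(u), vol_of(u * 1.02), gamma_criteria(3, 3))
  expect_equal(as.numeric(two_pct$gamma), rep(2 / 3, length(u)),
               tolerance = 1e-12)
  expect_equal(two_pct$pass_rate, 100)

  four_pct <- gamma_map(vol_of(u), vol_of(u * 1.04), gamma_criteria(3, 3))
  expect_equal(as.numeric(four_pct$gamma), rep(4 / 3, length(u)),
               tolerance = 1e-12)
  expect_equal(four_pct$pass_rate, 0)

  expect_error(gamma_map(vol_of(u * 0), vol_of(u)), "zero")
})

test_that("gamma map agrees with the exhaustive full-grid oracle", {
  with_test_seed(21, {
    base <- array(0, c(12, 12, 12))
    ctr <- c(6, 6, 6)
    for (i in 1:12) for (j in 1:12) for (k in 1:12)
      base[i, j, k] <- 50 * exp(-sum((c(i, j, k) - ctr)^2) / 40)
    ev <- base * (1 + array(rnorm(12^3, sd = 0.02), c(12, 12, 12))) +
      array(rnorm(12^3, sd = 0.3), c(12, 12, 12))
    ev <- pmax(ev, 0)
  })
  sp <- c(3, 3, 3)
  crit <- gamma_criteria(3, 3)
  gm <- gamma_map(vol_of(base, sp), vol_of(ev, sp), crit, refine_per_dta = 1)
  oracle <- gamma_oracle(base, ev, sp, dta = 3, tol_abs = 0.03 * max(base),
                         cutoff_abs = 0.1 * max(base))
  ok <- !is.na(oracle)
  expect_identical(ok, !is.na(gm$gamma))
  # radius-limited search may only truncate at gamma values far above 1
  expect_lt(max(abs(gm$gamma[ok] - oracle[ok])), 1e-6)
})

test_that("gamma passing rate is monotone as criteria loosen", {
  with_test_seed(22, {
    ref <- array(runif(10^3, 0, 60), c(10, 10, 10))
    ev <- ref + array(rnorm(10^3, sd = 2), c(10, 10, 10))
    ev <- pmax(ev, 0)
  })
  rates <- vapply(list(c(1, 1), c(2, 2), c(3, 3)), function(cr)
    gamma_map(vol_of(ref), vol_of(ev),
              gamma_criteria(cr[1], cr[2]))$pass_rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
  # doubling both tolerance and DTA never decreases the rate
  r11 <- gamma_map(vol_of(ref), vol_of(ev), gamma_criteria(2, 2))$pass_rate
  r22 <- gamma_map(vol_of(ref), vol_of(ev), gamma_criteria(4, 4))$pass_rate
  expect_gte(r22, r11)
})

test_that("DVH curves match direct counting and behave like CDFs", {
  d <- c(4, 8, 8)
  dose <- array(0, d)
  roi <- array(FALSE, d)
  roi[2:3, 3:6, 3:6] <- TRUE
  dose[roi] <- 50
  tab <- dvh(vol_of(dose), structure_set(list(ptv = roi)), bin_width = 1)
  ptv <- tab[tab$roi == "ptv", ]
  expect_equal(ptv$volume_pct[ptv$dose_gy == 0], 100)
  expect_equal(ptv$volume_pct[ptv$dose_gy == 50], 100)
  expect_equal(ptv$volume_pct[ptv$dose_gy == 51], 0)
  expect_true(all(diff(ptv$volume_pct) <= 0))

  half <- dose
  half[roi][seq_len(sum(roi) / 2)] <- 10
  half[roi][-seq_len(sum(roi) / 2)] <- 30
  t2 <- dvh(vol_of(half), structure_set(list(ptv = roi)), bin_width = 1)
  expect_equal(t2$volume_pct[t2$roi == "ptv" & t2$dose_gy == 20], 50)

  with_test_seed(23, rdose <- array(runif(prod(d), 0, 60), d))
  t3 <- dvh(vol_of(rdose), structure_set(list(ptv = roi)), bin_width = 0.5)
  v <- rdose[roi]
  for (row in sample(which(t3$roi == "ptv"), 25))
    expect_equal(t3$volume_pct[row], 100 * mean(v >= t3$dose_gy[row]),
                 tolerance = 1e-12)
})

test_that("DVH parameters match sort-based oracles", {
  p <- tiny_phantom()
  uni <- array(0, dim(p$ct$data))
  uni[p$rois$ptv] <- 50
  uni[p$rois$cord] <- 50
  dv <- vol_of(uni, p$ct$spacing)
  dp <- dvh_params(dv, p$rois)
  expect_equal(dp$ptv_d98, 50)
  expect_equal(dp$cord_dmax, 50)

  lung <- p$rois$lung_total
  mixed <- array(0, dim(uni))
  mixed[lung][seq_len(sum(lung) / 2)] <- 4
  mixed[lung][-seq_len(sum(lung) / 2)] <- 6
  dp2 <- dvh_params(vol_of(mixed, p$ct$spacing), p$rois)
  expect_equal(dp2$lung_v5, 50, tolerance = 0.2)
  expect_equal(dp2$mld, 5, tolerance = 1e-3)   # odd voxel count: not exact

  dose <- make_dose(p$rois, 50.4, 5, spacing = p$ct$spacing)
  dp3 <- dvh_params(dose, p$rois)
  v <- sort(dose$data[p$rois$ptv], decreasing = TRUE)
  expect_equal(dp3$ptv_d98, v[ceiling(0.98 * length(v))], tolerance = 1e-9)
  no_cord <- structure_set(list(ptv = p$rois$ptv,
                                lung_total = p$rois$lung_total,
                                heart = p$rois$heart))
  expect_error(dvh_params(dose, no_cord), "cord")

  # mean dose from the differential histogram equals the voxel mean
  tab <- dvh(dose, p$rois, bin_width = 0.01)
  cur <- tab[tab$roi == "lung_total", ]
  diffh <- -diff(c(cur$volume_pct, 0)) / 100
  mean_from_hist <- sum(diffh * cur$dose_gy)
  expect_lt(abs(mean_from_hist - mean(dose$data[p$rois$lung_total])),
            0.02)
})
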