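test_that("body mask matches the phantom outline and tolerates noise", {
  p <- tiny_phantom()
  bm <- body_mask(p$ct)
  expect_gt(dice(bm, p$rois$body), 0.98)
  noisy <- p$ct
  noisy$data <- noisy$data + with_test_seed(2, array(rnorm(length(bm), sd = 20),
                                                     dim(bm)))
  expect_gt(dice(body_mask(noisy), bm), 0.995)
  air <- image_volume(array(-1000, c(4, 8, 8)))
  expect_error(body_mask(air), "empty")
})

test_that("image similarity matches a brute-force oracle and closed forms", {
  p <- tiny_phantom()
  mask <- p$rois$body
  ref <- p$ct
  same <- image_similarity(ref, ref, mask)
  expect_equal(same$mae, 0)
  expect_equal(same$rmse, 0)
  expect_identical(same$psnr, Inf)

  plus10 <- image_volume(ref$data + 10, ref$spacing, ref$origin)
  s10 <- image_similarity(plus10, ref, mask)
  expect_equal(s10$mae, 10, tolerance = 1e-9)
  expect_equal(s10$rmse, 10, tolerance = 1e-9)
  expect_equal(s10$psnr, 20 * log10(300), tolerance = 1e-9)

  with_test_seed(3, {
    a <- image_volume(array(rnorm(16^3, sd = 50), c(16, 16, 16)))
    b <- image_volume(array(rnorm(16^3, sd = 50), c(16, 16, 16)))
    m <- array(runif(16^3) > 0.3, c(16, 16, 16))
  })
  s <- image_similarity(a, b, m)
  # element-by-element oracle
  dif <- as.numeric(a$data)[as.logical(m)] - as.numeric(b$data)[as.logical(m)]
  expect_lt(abs(s$mae - sum(abs(dif)) / length(dif)), 1e-9)
  expect_lt(abs(s$rmse - sqrt(sum(dif^2) / length(dif))), 1e-9)
  expect_lte(s$mae, s$rmse)   # power-mean inequality
})

test_that("PSNR decreases as independent noise grows", {
  p <- tiny_phantom()
  mask <- p$rois$body
  psnr <- vapply(c(10, 50, 100), function(sd) {
    noisy <- p$ct
    noisy$data <- noisy$data +
      with_test_seed(sd, array(rnorm(length(mask), sd = sd), dim(mask)))
    image_similarity(noisy, p$ct, mask)$psnr
  }, numeric(1))
  expect_true(all(diff(psnr) < 0))
})

test_that("similarity metrics are invariant to joint voxel permutation", {
  with_test_seed(8, {
    a <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
    b <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
    m <- array(runif(120) > 0.4, c(4, 5, 6))
    perm <- sample(120)
  })
  s1 <- image_similarity(image_volume(a), image_volume(b), m)
  s2 <- image_similarity(image_volume(array(a[perm], dim(a))),
                         image_volume(array(b[perm], dim(b))),
                         array(m[perm], dim(m)))
  expect_equal(s1[c("mae", "rmse", "psnr")], s2[c("mae", "rmse", "psnr")],
               tolerance = 1e-12)
})

test_that("ROI statistics match their definitions", {
  vol <- image_volume(array(0, c(2, 10, 10)))
  roi <- array(FALSE, c(2, 10, 10))
  roi[1, 1:5, 1:10] <- TRUE
  vol$data[roi] <- 100
  st <- roi_stats(vol, structure_set(list(fifty = roi)))
  expect_equal(st$mean, 100)
  expect_equal(st$sd, 0)
  expect_equal(st$median, 100)
  expect_equal(st$integral, 5000)
  expect_equal(st$count, 50L)

  two <- array(FALSE, c(2, 10, 10))
  two[2, 1, 1:2] <- TRUE
  vol$data[two] <- c(-900, -700)
  st2 <- roi_stats(vol, structure_set(list(pair = two)))
  expect_equal(st2[, c("mean", "median", "min", "max")],
               data.frame(mean = -800, median = -800, min = -900,
                          max = -700))

  empty <- structure_set(list(none = array(FALSE, c(2, 10, 10)),
                              pair = two))
  ste <- roi_stats(vol, empty)
  expect_true(ste$empty[ste$roi == "none"])
  expect_true(is.na(ste$mean[ste$roi == "none"]))

  # integral = mean * count on arbitrary input
  p <- tiny_phantom()
  st3 <- roi_stats(p$ct, p$rois)
  ok <- !st3$empty
  expect_lt(max(abs(st3$integral[ok] - st3$mean[ok] * st3$count[ok]) /
                  pmax(1, abs(st3$integral[ok]))), 1e-6)
})

test_that("HU histograms conserve counts and find the lung peak", {
  p <- tiny_phantom()
  h <- hu_histogram(p$ct, p$rois$body)
  expect_equal(sum(h$count), sum(p$rois$body))
  low <- h[h$center < -400, ]
  expect_lt(abs(low$center[which.max(low$count)] - (-900)), 10)
  const <- image_volume(array(123.4, c(3, 4, 5)))
  hc <- hu_histogram(const, array(TRUE, c(3, 4, 5)))
  expect_equal(sum(hc$count > 0), 1)
})

test_that("paired Wilcoxon matches an exhaustive sign-flip oracle at n = 8", {
  with_test_seed(11, {
    a <- rnorm(8)
    b <- a + rnorm(8, sd = 0.8)
  })
  res <- paired_compare(a, b)
  d <- a - b
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  expect_equal(res$statistic, v_obs)
  # exact two-sided p by enumerating all 2^8 sign assignments
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  v_all <- signs %*% r
  p_exact <- mean(pmin(1, 2 * pmin(mean(v_all <= v_obs),
                                   mean(v_all >= v_obs))))
  expect_equal(res$p, p_exact, tolerance = 1e-12)
})

test_that("paired Wilcoxon handles shifts and degenerate ties", {
  with_test_seed(12, a <- rnorm(20))
  res <- paired_compare(a + 1, a)
  expect_true(res$significant)
  expect_lt(res$p, 0.05)
  same <- paired_compare(a, a)
  expect_true(same$degenerate)
  expect_false(same$significant)
  expect_error(paired_compare(1:4, 1:4), "at least 5")
  expect_error(paired_compare(1:6, 1:5), "length")
})
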