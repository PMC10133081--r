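test_that("loss identities hold exactly", {
  a <- matrix(runif(64), 8, 8)
  expect_identical(correction_loss(a, a), 0)
  expect_equal(correction_loss(a + 0.1, a), 0.1, tolerance = 1e-12)
  expect_error(correction_loss(a, matrix(0, 4, 4)), "mismatch")
  with_test_seed(1, {
    u <- matrix(rnorm(64), 8, 8)
    v <- matrix(rnorm(64), 8, 8)
  })
  expect_lt(abs(correction_loss(u, v) - mean(abs(u - v))), 1e-9)

  expect_identical(smooth_loss(array(0, c(6, 6, 2))), 0)
  expect_identical(smooth_loss(array(3.7, c(6, 6, 2))), 0)
  ramp <- array(0, c(6, 6, 2))
  ramp[, , 1] <- matrix(0:5, 6, 6)          # slope 1 along rows
  expect_equal(smooth_loss(ramp), 1, tolerance = 1e-12)

  ones <- matrix(1, 4, 4)
  zeros <- matrix(0, 4, 4)
  expect_equal(adversarial_loss(ones, zeros, "discriminator"), 0)
  expect_equal(adversarial_loss(NULL, ones, "generator"), 0)
  expect_equal(adversarial_loss(NULL, zeros, "generator"), 1)

  expect_equal(total_loss(0.5, 0.01, 2.0), 40.6)
  expect_equal(total_loss(0, 0, 0), 0)
  expect_equal(total_loss(0.37, 5, 9, c(1, 0, 0)), 0.37)
})

test_that("training is deterministic under a fixed seed", {
  p <- tiny_phantom()
  nv <- clip_normalize(p$ct)$data
  ds <- lapply(5:8, function(k) list(x = nv[k, , ], y = nv[k + 1, , ]))
  cfg <- train_config(epochs = 2, ngf = 2, ndf = 2, nrf = 2, n_residual = 1,
                      lr = 1e-3, seed = 42)
  r1 <- train(ds, cfg)
  r2 <- train(ds, cfg)
  expect_identical(r1$history, r2$history)
})

test_that("zero weights silence correction/smooth gradients but not records", {
  ns <- asNamespace("regganct")
  with_test_seed(9, {
    G <- build_generator(2, 1)
    D <- build_discriminator(2)
    R <- build_regnet(2)
    # perturb R's head so the field (and smooth loss) is nonzero
    R$layers$out$W <- matrix(rnorm(length(R$layers$out$W), sd = 0.02),
                             nrow(R$layers$out$W))
    x <- matrix(runif(64 * 64, -1, 1), 64, 64)
    y <- matrix(runif(64 * 64, -1, 1), 64, 64)
  })
  cfg0 <- train_config(lambda_corr = 0, lambda_smooth = 0, ngf = 2, ndf = 2,
                       nrf = 2)
  st0 <- ns$reggan_step_grads(G, D, R, x, y, cfg0)
  expect_gt(st0$losses[["corr"]], 0)     # still reported
  expect_gt(st0$losses[["smooth"]], 0)
  # R receives no gradient when its losses carry zero weight
  gmax <- max(vapply(st0$gR[!vapply(st0$gR, is.null, TRUE)],
                     function(g) max(abs(g$W)), numeric(1)))
  expect_equal(gmax, 0)
  # G's gradient equals the pure adversarial gradient
  cfg1 <- train_config(ngf = 2, ndf = 2, nrf = 2)
  st1 <- ns$reggan_step_grads(G, D, R, x, y, cfg1)
  expect_false(isTRUE(all.equal(st0$gG[[1]]$W, st1$gG[[1]]$W)))
  fwG <- generator_forward(G, x, cache = TRUE)
  fwD <- discriminator_forward(D, fwG$out, cache = TRUE)
  dscore <- array(2 * (fwD$out - 1) / length(fwD$out), c(dim(fwD$out), 1))
  dfake <- ns$seq_backward(D, fwD$caches, dscore)$dx
  gadv <- ns$seq_backward(G, fwG$caches, dfake)$grads
  expect_equal(st0$gG[[1]]$W, gadv[[1]]$W, tolerance = 1e-10)
})

test_that("non-finite losses abort with the offending term named", {
  ns <- asNamespace("regganct")
  expect_error(ns$check_finite_losses(c(corr = NaN, smooth = 1), "epoch 1"),
               "corr")
})

test_that("registration-only training reduces the correction loss", {
  p <- tiny_phantom()
  nv <- clip_normalize(p$ct)$data
  y <- nv[8, , ]
  f <- smooth_field_2d(64, 64, mag = 2, seed = 3)
  pairs <- list(list(x = y, y = warp(y, f)))
  tr <- train_regnet(pairs, iters = 30, nrf = 8, seed = 1)
  expect_lt(tail(tr$corr, 1), tr$corr[1])
})
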