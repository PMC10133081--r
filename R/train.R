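# The three-term training objective and the training recipe: the
# generator and registration network are updated jointly against
# lambda_adv * L_adv + lambda_smooth * L_smooth + lambda_corr * L_corr,
# the discriminator against its least-squares adversarial loss.

#' Training configuration
#'
#' Defaults follow the published recipe: Adam at learning rate 1e-4 with
#' betas (0.5, 0.999), batch size 1, weight decay 1e-4, 50 epochs, and
#' loss weights lambda_adv = 1, lambda_smooth = 10, lambda_corr = 20.
#' Network widths are configuration, not architecture, and may be
#' reduced for desk-scale runs.
#'
#' @param lr Adam learning rate.
#' @param betas Adam (beta1, beta2).
#' @param batch_size slices per step (the recipe uses 1).
#' @param weight_decay L2 weight decay folded into the gradient.
#' @param epochs training epochs.
#' @param lambda_adv,lambda_smooth,lambda_corr loss weights.
#' @param seed run seed (shuffling and initialization).
#' @param ngf,ndf,nrf base channel widths of G, D and R.
#' @param n_residual residual blocks in the generator.
#' @param g_norm generator feature normalization (`"instance"`/`"none"`).
#' @param regnet_warmup iterations of registration-network warm-up on
#'   (CBCT, CT) slice pairs before joint training (0 = none). Warming R
#'   up means the generator's correction gradients are spatially
#'   aligned from the first joint iteration — important at small
#'   iteration budgets.
#' @param gen_pretrain iterations of generator reconstruction
#'   pretraining (L1 autoencoding of the label slices) before joint
#'   training (0 = none).
#' @param pretrain_lr learning rate used for both warm-up phases.
#' @param ema_decay exponential-moving-average decay for the generator
#'   weights; the averaged generator is what inference uses (0 = off).
#'   Weight averaging damps the iteration-to-iteration oscillation of
#'   adversarial training.
#' @param checkpoint_every write an intermediate checkpoint every this
#'   many epochs (0 = only at the end).
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-4, betas = c(0.5, 0.999), batch_size = 1L,
                         weight_decay = 1e-4, epochs = 50L,
                         lambda_adv = 1, lambda_smooth = 10,
                         lambda_corr = 20, seed = 1L, ngf = 64L, ndf = 64L,
                         nrf = 32L, n_residual = 9L, g_norm = "instance",
                         regnet_warmup = 0L, gen_pretrain = 0L,
                         pretrain_lr = 1e-3, ema_decay = 0,
                         checkpoint_every = 0L) {
  if (any(c(lr, weight_decay, lambda_adv, lambda_smooth, lambda_corr) < 0))
    stop("rates and loss weights must be >= 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(lr = lr, betas = betas, batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 lambda_adv = lambda_adv, lambda_smooth = lambda_smooth,
                 lambda_corr = lambda_corr, seed = as.integer(seed),
                 ngf = as.integer(ngf), ndf = as.integer(ndf),
                 nrf = as.integer(nrf), n_residual = as.integer(n_residual),
                 g_norm = g_norm,
                 regnet_warmup = as.integer(regnet_warmup),
                 gen_pretrain = as.integer(gen_pretrain),
                 pretrain_lr = pretrain_lr, ema_decay = ema_decay,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "train_config")
}

#' Correction loss
#'
#' Mean absolute difference between the registration-corrected generated
#' slice `warp(G(x), R(G(x), y))` and the label slice `y` (L1 form).
#'
#' @param warped_sct,y 2D matrices of the same shape.
#' @return scalar >= 0.
#' @export
correction_loss <- function(warped_sct, y) {
  if (!identical(dim(warped_sct), dim(y))) stop("shape mismatch")
  mean(abs(warped_sct - y))
}

#' Smoothness loss of a displacement field
#'
#' Sum, over field components and spatial axes, of the mean squared
#' forward finite difference: zero exactly for spatially constant
#' fields, and a unit ramp contributes 1 from its component/axis pair.
#'
#' @param field array `(H, W, 2)`.
#' @return scalar >= 0.
#' @export
smooth_loss <- function(field) {
  d <- dim(field)
  total <- 0
  for (comp in 1:2) {
    f <- field[, , comp]
    dr <- f[-1, , drop = FALSE] - f[-d[1], , drop = FALSE]
    dc <- f[, -1, drop = FALSE] - f[, -d[2], drop = FALSE]
    total <- total + mean(dr^2) + mean(dc^2)
  }
  total
}

smooth_loss_grad <- function(field) {
  d <- dim(field)
  g <- array(0, d)
  for (comp in 1:2) {
    f <- field[, , comp]
    dr <- f[-1, , drop = FALSE] - f[-d[1], , drop = FALSE]
    dc <- f[, -1, drop = FALSE] - f[, -d[2], drop = FALSE]
    gr <- matrix(0, d[1], d[2])
    gr[-1, ] <- gr[-1, ] + 2 * dr / length(dr)
    gr[-d[1], ] <- gr[-d[1], ] - 2 * dr / length(dr)
    gr[, -1] <- gr[, -1] + 2 * dc / length(dc)
    gr[, -d[2]] <- gr[, -d[2]] - 2 * dc / length(dc)
    g[, , comp] <- gr
  }
  g
}

#' Least-squares adversarial loss
#'
#' Discriminator role: `0.5 * (mean((d_real - 1)^2) + mean(d_fake^2))`
#' (target 1 on real, 0 on fake). Generator role:
#' `mean((d_fake - 1)^2)` (target 1 on fake).
#'
#' @param d_real,d_fake score matrices (`d_real` ignored for the
#'   generator role).
#' @param role `"generator"` or `"discriminator"`.
#' @return scalar >= 0.
#' @export
adversarial_loss <- function(d_real, d_fake, role = c("generator",
                                                      "discriminator")) {
  role <- match.arg(role)
  if (!is.null(d_real) && !identical(dim(d_real), dim(d_fake)))
    stop("score shapes do not match")
  if (role == "generator") mean((d_fake - 1)^2)
  else 0.5 * (mean((d_real - 1)^2) + mean(d_fake^2))
}

#' Weighted total loss
#'
#' `lambda_adv * adv + lambda_smooth * smooth + lambda_corr * corr`
#' with default weights (1, 10, 20).
#'
#' @param adv,smooth,corr loss components.
#' @param weights numeric length-3 `(adv, smooth, corr)`.
#' @return scalar.
#' @export
total_loss <- function(adv, smooth, corr, weights = c(1, 10, 20)) {
  weights[1] * adv + weights[2] * smooth + weights[3] * corr
}

# --- one optimization step --------------------------------------------------

# Computes all losses and gradients for one (x, y) slice pair. Exposed
# internally so gradient-flow properties can be tested in isolation.
reggan_step_grads <- function(G, D, R, x, y, cfg) {
  fwG <- generator_forward(G, x, cache = TRUE)
  fake <- fwG$out

  # discriminator gradients (fake detached)
  fwDr <- discriminator_forward(D, y, cache = TRUE)
  fwDf <- discriminator_forward(D, fake, cache = TRUE)
  loss_d <- adversarial_loss(fwDr$out, fwDf$out, "discriminator")
  nd <- length(fwDf$out)
  dreal <- array((fwDr$out - 1) / nd, c(dim(fwDr$out), 1))
  dfake_s <- array(fwDf$out / nd, c(dim(fwDf$out), 1))
  gD <- grads_add(seq_backward(D, fwDr$caches, dreal)$grads,
                  seq_backward(D, fwDf$caches, dfake_s)$grads)

  # generator + registration gradients
  fwR <- regnet_forward(R, fake, y, cache = TRUE)
  field <- fwR$field
  warped <- warp(fake, field)
  loss_corr <- correction_loss(warped, y)
  loss_smooth <- smooth_loss(field)
  fwDf2 <- discriminator_forward(D, fake, cache = TRUE)
  loss_adv_g <- adversarial_loss(NULL, fwDf2$out, "generator")
  loss_total <- total_loss(loss_adv_g, loss_smooth, loss_corr,
                           c(cfg$lambda_adv, cfg$lambda_smooth,
                             cfg$lambda_corr))

  dwarped <- cfg$lambda_corr * sign(warped - y) / length(y)
  bw_warp <- warp_backward(fake, field, dwarped)
  dfield <- bw_warp$dfield +
    cfg$lambda_smooth * smooth_loss_grad(field)
  bw_R <- regnet_backward(R, fwR$caches, dfield)
  dfake <- bw_warp$dimg + matrix(bw_R$dx[, , 1], nrow(x), ncol(x))
  dscore <- array(cfg$lambda_adv * 2 * (fwDf2$out - 1) / nd,
                  c(dim(fwDf2$out), 1))
  dfake <- dfake + matrix(seq_backward(D, fwDf2$caches, dscore)$dx[, , 1],
                          nrow(x), ncol(x))
  gG <- if (isTRUE(G$identity)) NULL else
    seq_backward(G, fwG$caches, array(dfake, c(dim(x), 1)))$grads

  list(losses = c(adv_g = loss_adv_g, adv_d = loss_d, corr = loss_corr,
                  smooth = loss_smooth, total = loss_total),
       gG = gG, gD = gD, gR = bw_R$grads)
}

check_finite_losses <- function(losses, where) {
  bad <- names(losses)[!is.finite(losses)]
  if (length(bad))
    stop(sprintf("non-finite loss term(s) %s at %s; aborting",
                 paste(bad, collapse = ", "), where))
}

#' Train the translation model
#'
#' Alternating updates (discriminator once, then generator and
#' registration network jointly once per slice pair), Adam with the
#' configured weights, slice order shuffled per epoch under the run
#' seed. One loss record per epoch (means over its iterations).
#'
#' @param dataset list of slice pairs, each `list(x = , y = )` with 2D
#'   matrices in `[-1, 1]` (build one with [slice_dataset()]).
#' @param cfg a [train_config()].
#' @param checkpoint_path optional path for the final checkpoint.
#' @param verbose print one line per epoch.
#' @return list with `G`, `D`, `R`, `history` (data.frame: epoch, adv_g,
#'   adv_d, corr, smooth, total) and `cfg`.
#' @export
train <- function(dataset, cfg = train_config(), checkpoint_path = NULL,
                  verbose = FALSE) {
  if (length(dataset) == 0) stop("dataset is empty")
  set.seed(cfg$seed)
  G <- build_generator(cfg$ngf, cfg$n_residual, cfg$g_norm)
  D <- build_discriminator(cfg$ndf)
  R <- build_regnet(cfg$nrf)
  stG <- adam_init(G)
  stD <- adam_init(D)
  stR <- adam_init_named(R)
  tG <- 0L
  tD <- 0L
  tR <- 0L
  G_out <- function() if (cfg$ema_decay > 0) Gema else G
  # generator reconstruction pretraining (label -> label, L1)
  for (t in seq_len(cfg$gen_pretrain)) {
    pair <- dataset[[(t - 1L) %% length(dataset) + 1L]]
    fw <- generator_forward(G, pair$y, cache = TRUE)
    dd <- sign(fw$out - pair$y) / length(pair$y)
    g <- seq_backward(G, fw$caches, array(dd, c(dim(dd), 1)))$grads
    tG <- tG + 1L
    up <- adam_step(G, g, stG, tG, cfg$pretrain_lr, cfg$betas[1],
                    cfg$betas[2], wd = cfg$weight_decay)
    G <- up$net
    stG <- up$state
  }
  Gema <- G
  ema_mix <- function(a, b, d) {
    for (i in seq_along(a$layers)) {
      la <- a$layers[[i]]
      lb <- b$layers[[i]]
      if (la$type %in% c("conv", "convt")) {
        la$W <- d * la$W + (1 - d) * lb$W
        la$b <- d * la$b + (1 - d) * lb$b
      } else if (la$type == "resblock") {
        for (j in seq_along(la$sub)) {
          if (la$sub[[j]]$type == "conv") {
            la$sub[[j]]$W <- d * la$sub[[j]]$W + (1 - d) * lb$sub[[j]]$W
            la$sub[[j]]$b <- d * la$sub[[j]]$b + (1 - d) * lb$sub[[j]]$b
          }
        }
      }
      a$layers[[i]] <- la
    }
    a
  }
  # registration-network warm-up on the raw (x, y) pairs
  for (t in seq_len(cfg$regnet_warmup)) {
    pair <- dataset[[(t - 1L) %% length(dataset) + 1L]]
    fwR <- regnet_forward(R, pair$x, pair$y, cache = TRUE)
    warped <- warp(pair$x, fwR$field)
    dwarped <- cfg$lambda_corr * sign(warped - pair$y) / length(pair$y)
    bw <- warp_backward(pair$x, fwR$field, dwarped)
    dfield <- bw$dfield + cfg$lambda_smooth * smooth_loss_grad(fwR$field)
    bwR <- regnet_backward(R, fwR$caches, dfield)
    tR <- tR + 1L
    up <- adam_step_named(R, bwR$grads, stR, tR, cfg$pretrain_lr,
                          cfg$betas[1], cfg$betas[2], wd = cfg$weight_decay)
    R <- up$net
    stR <- up$state
  }
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(dataset))
    acc <- c(adv_g = 0, adv_d = 0, corr = 0, smooth = 0, total = 0)
    for (i in ord) {
      pair <- dataset[[i]]
      st <- reggan_step_grads(G, D, R, pair$x, pair$y, cfg)
      check_finite_losses(st$losses, sprintf("epoch %d", ep))
      tD <- tD + 1L
      up <- adam_step(D, st$gD, stD, tD, cfg$lr, cfg$betas[1], cfg$betas[2],
                      wd = cfg$weight_decay)
      D <- up$net
      stD <- up$state
      tG <- tG + 1L
      up <- adam_step(G, st$gG, stG, tG, cfg$lr, cfg$betas[1], cfg$betas[2],
                      wd = cfg$weight_decay)
      G <- up$net
      stG <- up$state
      if (cfg$ema_decay > 0)
        Gema <- ema_mix(Gema, G, cfg$ema_decay)
      tR <- tR + 1L
      upR <- adam_step_named(R, st$gR, stR, tR, cfg$lr, cfg$betas[1],
                             cfg$betas[2], wd = cfg$weight_decay)
      R <- upR$net
      stR <- upR$state
      acc <- acc + st$losses[names(acc)]
    }
    acc <- acc / length(dataset)
    hist[[ep]] <- data.frame(epoch = ep, adv_g = acc["adv_g"],
                             adv_d = acc["adv_d"], corr = acc["corr"],
                             smooth = acc["smooth"], total = acc["total"],
                             row.names = NULL)
    if (verbose)
      message(sprintf(
        "epoch %d/%d  adv_g %.4f  adv_d %.4f  corr %.4f  smooth %.5f",
        ep, cfg$epochs, acc["adv_g"], acc["adv_d"], acc["corr"],
        acc["smooth"]))
    if (!is.null(checkpoint_path) && cfg$checkpoint_every > 0 &&
        ep %% cfg$checkpoint_every == 0)
      save_checkpoint(checkpoint_path, G_out(), D, R, cfg)
  }
  history <- do.call(rbind, hist)
  if (!is.null(checkpoint_path))
    save_checkpoint(checkpoint_path, G_out(), D, R, cfg)
  list(G = G_out(), D = D, R = R, history = history, cfg = cfg)
}

# Adam over the named layer list of the registration network.
adam_init_named <- function(R) lapply(R$layers, adam_init_layer)

adam_step_named <- function(R, grads, state, t, lr, b1, b2, wd) {
  for (nm in names(R$layers)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    up <- adam_update_layer(R$layers[[nm]], g, state[[nm]], t, lr, b1, b2,
                            1e-8, wd)
    R$layers[[nm]] <- up$layer
    state[nm] <- list(up$st)
  }
  list(net = R, state = state)
}

#' Train the registration network alone
#'
#' Freezes the generator as the identity and fits R on (moving, fixed)
#' slice pairs with the correction + smoothness objective; used to
#' verify that R recovers known smooth deformations.
#'
#' @param pairs list of `list(x = moving, y = fixed)` matrices.
#' @param iters total optimization iterations (one pair per iteration,
#'   cycled in order).
#' @param lr learning rate (desk-scale default 1e-3).
#' @param lambda_smooth,lambda_corr loss weights.
#' @param nrf base width of R.
#' @param seed initialization seed.
#' @return list with `R` and a loss vector (`corr` per iteration).
#' @export
train_regnet <- function(pairs, iters = 200L, lr = 2e-3, lambda_smooth = 10,
                         lambda_corr = 20, nrf = 32L, seed = 1L) {
  stopifnot(length(pairs) >= 1)
  set.seed(seed)
  R <- build_regnet(nrf)
  st <- adam_init_named(R)
  losses <- numeric(iters)
  for (t in seq_len(iters)) {
    pair <- pairs[[(t - 1L) %% length(pairs) + 1L]]
    x <- pair$x
    y <- pair$y
    fwR <- regnet_forward(R, x, y, cache = TRUE)
    field <- fwR$field
    warped <- warp(x, field)
    lc <- correction_loss(warped, y)
    ls <- smooth_loss(field)
    check_finite_losses(c(corr = lc, smooth = ls), sprintf("iter %d", t))
    dwarped <- lambda_corr * sign(warped - y) / length(y)
    bw <- warp_backward(x, field, dwarped)
    dfield <- bw$dfield + lambda_smooth * smooth_loss_grad(field)
    bwR <- regnet_backward(R, fwR$caches, dfield)
    up <- adam_step_named(R, bwR$grads, st, t, lr, 0.9, 0.999, wd = 0)
    R <- up$net
    st <- up$state
    losses[t] <- lc
  }
  list(R = R, corr = losses)
}

#' Build a slice-pair training set from volumes
#'
#' Clip-normalizes each volume and pairs axial slices by index:
#' x = CBCT slice, y = planning-CT slice (the misaligned label).
#'
#' @param cbct,planning [image_volume()]s on the same grid.
#' @return list of `list(x, y)` matrices.
#' @export
slice_dataset <- function(cbct, planning) {
  stopifnot(identical(dim(cbct$data), dim(planning$data)))
  nx <- clip_normalize(cbct)$data
  ny <- clip_normalize(planning)$data
  lapply(seq_len(dim(nx)[1]), function(k)
    list(x = nx[k, , ], y = ny[k, , ]))
}

#' Write per-epoch loss curves as CSV
#'
#' @param history data.frame from [train()].
#' @param path CSV path.
#' @export
write_loss_curves <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
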