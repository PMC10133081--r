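# Minimal CNN framework: layers with explicit forward/backward passes on
# (H, W, C) arrays, backed by im2col/GEMM kernels, plus an Adam optimizer.
# This is deliberately small: only what the translation model needs.

# weight init for conv layers: "gaussian" N(0, 0.02) (the standard GAN
# translator init) or "he" scaled by fan-in
conv_init <- function(nout, fanin, init) {
  if (init == "he")
    matrix(stats::rnorm(nout * fanin, sd = sqrt(2 / fanin)), nout, fanin)
  else matrix(stats::rnorm(nout * fanin, sd = 0.02), nout, fanin)
}

lay_conv <- function(in_ch, out_ch, k, s = 1, p = 0, zero = FALSE,
                     init = "gaussian") {
  W <- if (zero) matrix(0, out_ch, in_ch * k * k) else
    conv_init(out_ch, in_ch * k * k, init)
  list(type = "conv", W = W, b = numeric(out_ch), k = k, s = s, p = p,
       in_ch = in_ch, out_ch = out_ch)
}

lay_convt <- function(in_ch, out_ch, k = 4, s = 2, p = 1,
                      init = "gaussian") {
  W <- t(conv_init(out_ch * k * k, in_ch, init))
  list(type = "convt", W = W, b = numeric(out_ch), k = k, s = s, p = p,
       in_ch = in_ch, out_ch = out_ch)
}

lay_inorm <- function() list(type = "inorm", eps = 1e-5)
lay_relu <- function() list(type = "relu")
lay_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
lay_tanh <- function() list(type = "tanh")
lay_resblock <- function(ch, norm = "instance") {
  sub <- if (norm == "instance")
    list(lay_conv(ch, ch, 3, 1, 1), lay_inorm(), lay_relu(),
         lay_conv(ch, ch, 3, 1, 1), lay_inorm())
  else
    list(lay_conv(ch, ch, 3, 1, 1), lay_relu(),
         lay_conv(ch, ch, 3, 1, 1))
  list(type = "resblock", sub = sub)
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      out <- conv2d_fwd_cpp(x, layer$W, layer$b, layer$k, layer$s, layer$p)
      list(out = out, cache = x)
    },
    convt = {
      out <- convt2d_fwd_cpp(x, layer$W, layer$b, layer$k, layer$s, layer$p)
      list(out = out, cache = x)
    },
    inorm = {
      d <- dim(x)
      mu <- colMeans(matrix(x, d[1] * d[2], d[3]))
      xc <- sweep(matrix(x, d[1] * d[2], d[3]), 2, mu)
      sd <- sqrt(colMeans(xc^2) + layer$eps)
      xhat <- sweep(xc, 2, sd, "/")
      list(out = array(xhat, d), cache = list(xhat = xhat, sd = sd, d = d))
    },
    relu = {
      out <- pmax(x, 0)
      list(out = out, cache = x > 0)
    },
    lrelu = {
      pos <- x > 0
      out <- x * ifelse(pos, 1, layer$alpha)
      list(out = out, cache = pos)
    },
    tanh = {
      out <- tanh(x)
      list(out = out, cache = out)
    },
    resblock = {
      h <- x
      caches <- vector("list", length(layer$sub))
      for (i in seq_along(layer$sub)) {
        fw <- layer_forward(layer$sub[[i]], h)
        h <- fw$out
        caches[[i]] <- fw$cache
      }
      list(out = x + h, cache = caches)
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      bw <- conv2d_bwd_cpp(cache, layer$W, dout, layer$k, layer$s, layer$p)
      list(dx = bw$dx, grads = list(W = bw$dW, b = as.numeric(bw$db)))
    },
    convt = {
      bw <- convt2d_bwd_cpp(cache, layer$W, dout, layer$k, layer$s, layer$p)
      list(dx = bw$dx, grads = list(W = bw$dW, b = as.numeric(bw$db)))
    },
    inorm = {
      d <- cache$d
      dy <- matrix(dout, d[1] * d[2], d[3])
      xhat <- cache$xhat
      m1 <- colMeans(dy)
      m2 <- colMeans(dy * xhat)
      dx <- sweep(dy, 2, m1) - sweep(xhat, 2, m2, "*")
      dx <- sweep(dx, 2, cache$sd, "/")
      list(dx = array(dx, d), grads = NULL)
    },
    relu = list(dx = dout * cache, grads = NULL),
    lrelu = list(dx = dout * ifelse(cache, 1, layer$alpha), grads = NULL),
    tanh = list(dx = dout * (1 - cache^2), grads = NULL),
    resblock = {
      dh <- dout
      grads <- vector("list", length(layer$sub))
      for (i in rev(seq_along(layer$sub))) {
        bw <- layer_backward(layer$sub[[i]], cache[[i]], dh)
        dh <- bw$dx
        grads[i] <- list(bw$grads)   # may be NULL; keep the slot
      }
      list(dx = dout + dh, grads = grads)
    },
    stop("unknown layer type: ", layer$type))
}

seq_forward <- function(net, x) {
  caches <- vector("list", length(net$layers))
  h <- x
  for (i in seq_along(net$layers)) {
    fw <- layer_forward(net$layers[[i]], h)
    h <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = h, caches = caches)
}

seq_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  dh <- dout
  for (i in rev(seq_along(net$layers))) {
    bw <- layer_backward(net$layers[[i]], caches[[i]], dh)
    dh <- bw$dx
    grads[i] <- list(bw$grads)   # may be NULL; keep the slot
  }
  list(dx = dh, grads = grads)
}

# --- gradient bookkeeping ---------------------------------------------------

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(mapply(grads_add, a, b, SIMPLIFY = FALSE))
  a + b
}

grads_scale <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) return(lapply(g, grads_scale, s = s))
  g * s
}

# --- Adam -------------------------------------------------------------------

adam_init_layer <- function(layer) {
  if (layer$type %in% c("conv", "convt"))
    list(mW = layer$W * 0, vW = layer$W * 0,
         mb = layer$b * 0, vb = layer$b * 0)
  else if (layer$type == "resblock")
    lapply(layer$sub, adam_init_layer)
  else NULL
}

adam_init <- function(net) lapply(net$layers, adam_init_layer)

adam_update_layer <- function(layer, grad, st, t, lr, b1, b2, eps, wd) {
  if (is.null(grad)) return(list(layer = layer, st = st))
  if (layer$type == "resblock") {
    for (i in seq_along(layer$sub)) {
      up <- adam_update_layer(layer$sub[[i]], grad[[i]], st[[i]],
                              t, lr, b1, b2, eps, wd)
      layer$sub[[i]] <- up$layer
      st[i] <- list(up$st)
    }
    return(list(layer = layer, st = st))
  }
  gW <- grad$W + wd * layer$W
  gb <- grad$b + wd * layer$b
  st$mW <- b1 * st$mW + (1 - b1) * gW
  st$vW <- b2 * st$vW + (1 - b2) * gW^2
  st$mb <- b1 * st$mb + (1 - b1) * gb
  st$vb <- b2 * st$vb + (1 - b2) * gb^2
  c1 <- 1 - b1^t
  c2 <- 1 - b2^t
  layer$W <- layer$W - lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
  layer$b <- layer$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
  list(layer = layer, st = st)
}

adam_step <- function(net, grads, state, t, lr, b1 = 0.5, b2 = 0.999,
                      eps = 1e-8, wd = 0) {
  for (i in seq_along(net$layers)) {
    up <- adam_update_layer(net$layers[[i]], grads[[i]], state[[i]],
                            t, lr, b1, b2, eps, wd)
    net$layers[[i]] <- up$layer
    state[i] <- list(up$st)
  }
  list(net = net, state = state)
}
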