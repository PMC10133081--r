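# The three networks of the translation model: generator G (residual
# translator), discriminator D (patch scores), registration network R
# (U-net emitting a per-pixel displacement field), plus the differentiable
# bilinear warping operator that applies R's field.

#' Build the generator network
#'
#' A residual translator: two stride-2 downsampling convolution blocks,
#' `n_residual` residual blocks, and two stride-2 upsampling
#' (de-convolution) blocks, with instance normalization and a final tanh
#' so the output stays in `[-1, 1]`. Maps a 1-channel slice to a
#' 1-channel slice of identical shape; spatial dims must be divisible
#' by 4 (two halvings).
#'
#' @param base_channels channels after the first convolution (>= 1).
#' @param n_residual number of residual blocks (default 9).
#' @param norm feature normalization: `"instance"` or `"none"`.
#' @return a `reggan_net` of kind `"generator"`.
#' @export
build_generator <- function(base_channels = 64L, n_residual = 9L,
                            norm = c("instance", "none")) {
  stopifnot(base_channels >= 1, n_residual >= 1)
  norm <- match.arg(norm)
  C <- as.integer(base_channels)
  nrm <- function() if (norm == "instance") list(lay_inorm()) else list()
  layers <- c(
    list(lay_conv(1, C, 7, 1, 3)), nrm(), list(lay_relu()),
    list(lay_conv(C, 2 * C, 3, 2, 1)), nrm(), list(lay_relu()),
    list(lay_conv(2 * C, 4 * C, 3, 2, 1)), nrm(), list(lay_relu()),
    lapply(seq_len(n_residual), function(i)
      lay_resblock(4 * C, norm = norm)),
    list(lay_convt(4 * C, 2 * C)), nrm(), list(lay_relu()),
    list(lay_convt(2 * C, C)), nrm(), list(lay_relu()),
    list(lay_conv(C, 1, 7, 1, 3), lay_tanh()))
  structure(list(kind = "generator", layers = layers,
                 base_channels = C, n_residual = as.integer(n_residual),
                 norm = norm),
            class = "reggan_net")
}

#' @export
print.reggan_net <- function(x, ...) {
  np <- sum(vapply(rapply(x$layers, function(p) length(p), how = "unlist"),
                   identity, numeric(1)))
  cat(sprintf("<reggan_net %s> %d layers\n", x$kind, length(x$layers)))
  invisible(x)
}

#' Run the generator on one normalized slice
#'
#' @param G generator from [build_generator()].
#' @param x 2D matrix in `[-1, 1]`.
#' @param cache return layer caches for backprop.
#' @return matrix of the same shape in `[-1, 1]` (or a list with caches).
#' @export
generator_forward <- function(G, x, cache = FALSE) {
  if (isTRUE(G$identity))
    return(if (cache) list(out = x, caches = NULL) else x)
  d <- dim(x)
  if (any(d %% 4 != 0))
    stop(sprintf("generator input dims (%d x %d) must be divisible by 4",
                 d[1], d[2]))
  fw <- seq_forward(G, array(x, c(d, 1)))
  out <- matrix(fw$out[, , 1], d[1], d[2])
  if (cache) list(out = out, caches = fw$caches) else out
}

#' Build the patch discriminator
#'
#' Four stride-2 convolution layers mapping a slice to an N x N score
#' matrix; each score judges a local patch of the input. N = H / 16.
#'
#' @param base_channels channels after the first convolution.
#' @return a `reggan_net` of kind `"discriminator"`.
#' @export
build_discriminator <- function(base_channels = 64L) {
  stopifnot(base_channels >= 1)
  C <- as.integer(base_channels)
  layers <- list(
    lay_conv(1, C, 4, 2, 1), lay_lrelu(),
    lay_conv(C, 2 * C, 4, 2, 1), lay_inorm(), lay_lrelu(),
    lay_conv(2 * C, 4 * C, 4, 2, 1), lay_inorm(), lay_lrelu(),
    lay_conv(4 * C, 1, 4, 2, 1))
  structure(list(kind = "discriminator", layers = layers,
                 base_channels = C), class = "reggan_net")
}

#' Run the discriminator
#'
#' @param D discriminator network.
#' @param x 2D matrix slice; dims must be divisible by 16 (four halvings).
#' @param cache return caches for backprop.
#' @return N x N score matrix.
#' @export
discriminator_forward <- function(D, x, cache = FALSE) {
  d <- dim(x)
  if (any(d < 16) || any(d %% 16 != 0))
    stop(sprintf("discriminator input dims (%d x %d) must be divisible by 16",
                 d[1], d[2]))
  fw <- seq_forward(D, array(x, c(d, 1)))
  out <- fw$out[, , 1]
  if (cache) list(out = out, caches = fw$caches) else out
}

#' Build the registration network
#'
#' A small U-net consuming the channel-concatenation of the generated
#' slice and the (possibly misaligned) label slice, and emitting a
#' 2-component per-pixel displacement field of the same spatial shape.
#' The final layer is zero-initialized so training starts from the
#' identity deformation.
#'
#' @param base_channels encoder width.
#' @return list of named layers with class `reggan_regnet`.
#' @export
build_regnet <- function(base_channels = 32L) {
  C <- as.integer(base_channels)
  structure(list(kind = "regnet", base_channels = C, layers = list(
    e1 = lay_conv(2, C, 3, 1, 1), e1a = lay_relu(),
    d1 = lay_conv(C, 2 * C, 3, 2, 1), d1a = lay_relu(),
    d2 = lay_conv(2 * C, 4 * C, 3, 2, 1), d2a = lay_relu(),
    bb = lay_conv(4 * C, 4 * C, 3, 1, 1), bba = lay_relu(),
    u2 = lay_convt(4 * C, 2 * C), u2a = lay_relu(),
    c2 = lay_conv(4 * C, 2 * C, 3, 1, 1), c2a = lay_relu(),
    u1 = lay_convt(2 * C, C), u1a = lay_relu(),
    c1 = lay_conv(2 * C, C, 3, 1, 1), c1a = lay_relu(),
    out = lay_conv(C, 2, 3, 1, 1, zero = TRUE))),
    class = "reggan_regnet")
}

#' Run the registration network
#'
#' @param R registration network from [build_regnet()].
#' @param g,y generated slice and label slice (same shape, dims
#'   divisible by 4).
#' @param cache return caches for backprop.
#' @return displacement field array `(H, W, 2)` in voxel units.
#' @export
regnet_forward <- function(R, g, y, cache = FALSE) {
  if (!identical(dim(g), dim(y)))
    stop("generated and label slices have different shapes")
  d <- dim(g)
  if (any(d %% 4 != 0))
    stop("registration network input dims must be divisible by 4")
  L <- R$layers
  cc <- list()
  x0 <- array(c(g, y), c(d, 2))
  f <- function(nm, x) {
    fw <- layer_forward(L[[nm]], x)
    cc[[nm]] <<- fw$cache
    fw$out
  }
  a1 <- f("e1a", f("e1", x0))
  a2 <- f("d1a", f("d1", a1))
  a3 <- f("d2a", f("d2", a2))
  a3 <- f("bba", f("bb", a3))
  u2 <- f("u2a", f("u2", a3))
  cat2 <- array(c(u2, a2), c(dim(u2)[1:2], dim(u2)[3] + dim(a2)[3]))
  b2 <- f("c2a", f("c2", cat2))
  u1 <- f("u1a", f("u1", b2))
  cat1 <- array(c(u1, a1), c(dim(u1)[1:2], dim(u1)[3] + dim(a1)[3]))
  b1 <- f("c1a", f("c1", cat1))
  field <- f("out", b1)
  if (cache) list(field = field, caches = cc) else field
}

regnet_backward <- function(R, caches, dfield) {
  L <- R$layers
  grads <- list()
  b <- function(nm, dout) {
    bw <- layer_backward(L[[nm]], caches[[nm]], dout)
    grads[[nm]] <<- bw$grads
    bw$dx
  }
  db1 <- b("out", dfield)
  dcat1 <- b("c1", b("c1a", db1))
  C <- dim(dcat1)[3] / 2
  du1 <- dcat1[, , seq_len(C), drop = FALSE]
  da1_skip <- dcat1[, , C + seq_len(C), drop = FALSE]
  db2 <- b("u1", b("u1a", du1))
  dcat2 <- b("c2", b("c2a", db2))
  C2 <- dim(dcat2)[3] / 2
  du2 <- dcat2[, , seq_len(C2), drop = FALSE]
  da2_skip <- dcat2[, , C2 + seq_len(C2), drop = FALSE]
  da3 <- b("u2", b("u2a", du2))
  da3 <- b("bb", b("bba", da3))
  da2 <- b("d2", b("d2a", da3)) + da2_skip
  da1 <- b("d1", b("d1a", da2)) + da1_skip
  dx0 <- b("e1", b("e1a", da1))
  list(dx = dx0, grads = grads)
}

#' Differentiable bilinear warp of a slice
#'
#' `out(p) = img(p + field(p))` by bilinear interpolation with border
#' clamping; differentiable with respect to both the image and the
#' field. Field units are voxels (row, col offsets).
#'
#' @param img 2D matrix.
#' @param field array `(H, W, 2)`.
#' @return warped 2D matrix.
#' @export
warp <- function(img, field) {
  if (!identical(dim(img), dim(field)[1:2]))
    stop("image and field have different spatial shapes")
  warp2d_fwd_cpp(img, field)
}

warp_backward <- function(img, field, dout) {
  warp2d_bwd_cpp(img, field, dout)
}

# --- checkpoints ------------------------------------------------------------

CHECKPOINT_VERSION <- "regganct-ckpt-1"

#' Save / load a training checkpoint
#'
#' Stores the three networks and the training configuration, with a
#' version tag validated on load.
#'
#' @param G,D,R networks; `cfg` the [train_config()] that produced them.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(path, G, D, R, cfg) {
  saveRDS(list(version = CHECKPOINT_VERSION, G = G, D = D, R = R,
               cfg = cfg), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt checkpoint (unreadable): ", conditionMessage(e)))
  if (!is.list(ck) || !identical(ck$version, CHECKPOINT_VERSION))
    stop(sprintf("corrupt checkpoint: expected version '%s', found '%s'",
                 CHECKPOINT_VERSION,
                 if (is.list(ck)) as.character(ck$version %||% "<none>")
                 else "<not a checkpoint>"))
  ck
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' An identity generator for harness use
#'
#' A generator stand-in whose forward pass returns its input unchanged;
#' useful for isolating the inference plumbing from training.
#' @export
identity_generator <- function() {
  structure(list(kind = "generator", layers = list(), identity = TRUE),
            class = "reggan_net")
}
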