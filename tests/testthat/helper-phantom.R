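# Shared fixtures, all generated in code at test time.

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

tiny_phantom <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- make_phantom(phantom_spec(seed = 7))
    memo
  }
})

# a random smooth 2D field with max Euclidean norm `mag`, via the same
# public generator used for 3D fields (thickness-1 volume)
smooth_field_2d <- function(h, w, mag, smooth = 8, seed = 1) {
  f3 <- with_test_seed(seed, {
    f <- random_smooth_field(c(1L, h, w), deform_spec(magnitude = mag,
                                                      smoothness = smooth,
                                                      seed = seed))
  })
  # keep the in-plane components only, rescaled to the magnitude bound
  f <- array(0, c(h, w, 2))
  f[, , 1] <- f3[1, , , 2]
  f[, , 2] <- f3[1, , , 3]
  nrm <- sqrt(f[, , 1]^2 + f[, , 2]^2)
  if (max(nrm) > 0) f <- f * (mag / max(nrm))
  f
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# independent 2D bilinear sampler (plain R), for warp oracles
bilinear_ref <- function(img, rr, cc) {
  H <- nrow(img); W <- ncol(img)
  rr <- min(max(rr, 0), H - 1); cc <- min(max(cc, 0), W - 1)
  r0 <- floor(rr); c0 <- floor(cc)
  r1 <- min(r0 + 1, H - 1); c1 <- min(c0 + 1, W - 1)
  fr <- rr - r0; fc <- cc - c0
  (1 - fr) * (1 - fc) * img[r0 + 1, c0 + 1] +
    (1 - fr) * fc * img[r0 + 1, c1 + 1] +
    fr * (1 - fc) * img[r1 + 1, c0 + 1] +
    fr * fc * img[r1 + 1, c1 + 1]
}
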