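# Data preparation: rigid alignment of planning CT to CBCT, center
# crop/resize, HU clipping + [-1,1] normalization, and multiresolution
# B-spline deformable registration to produce the dCT reference.

HU_CLIP <- c(-1000, 2000)
HU_MID <- 500
HU_HALF <- 1500

#' Clip HU to [-1000, 2000] and normalize to [-1, 1]
#'
#' The linear map `(clip(v, -1000, 2000) - 500) / 1500`, forced by mapping
#' the clip window onto `[-1, 1]`. Ultra-high bone HU is clipped so it
#' cannot dominate training.
#'
#' @param vol an [image_volume()] in HU.
#' @return a `normalized_volume`: same grid, values in `[-1, 1]`.
#' @export
clip_normalize <- function(vol) {
  stopifnot(is_volume(vol))
  v <- (pmin(pmax(vol$data, HU_CLIP[1]), HU_CLIP[2]) - HU_MID) / HU_HALF
  structure(list(data = array(v, dim(vol$data)), spacing = vol$spacing,
                 origin = vol$origin, frame = vol$frame),
            class = c("normalized_volume"))
}

#' Map a normalized volume back to HU
#'
#' Inverse of [clip_normalize()]: `v -> 1500 v + 500`. Input values must
#' lie in `[-1, 1]`.
#'
#' @param nv a `normalized_volume` (or plain array in `[-1, 1]`).
#' @param spacing,origin,frame grid info when `nv` is a plain array.
#' @return an [image_volume()] in HU.
#' @export
denormalize <- function(nv, spacing = NULL, origin = NULL, frame = "sct") {
  if (inherits(nv, "normalized_volume")) {
    v <- nv$data; spacing <- nv$spacing; origin <- nv$origin
  } else {
    v <- nv
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    if (is.null(origin)) origin <- c(0, 0, 0)
  }
  if (any(v < -1 - 1e-9) || any(v > 1 + 1e-9))
    stop("normalized values outside [-1, 1]")
  image_volume(array(HU_HALF * v + HU_MID, dim(v)), spacing, origin, frame)
}

normalize_slice <- function(m) (pmin(pmax(m, HU_CLIP[1]), HU_CLIP[2]) - HU_MID) / HU_HALF
denormalize_slice <- function(m) HU_HALF * m + HU_MID

#' Center crop / pad and resample to a target grid
#'
#' If the target spacing differs from the input, the volume is first
#' trilinearly resampled (center-aligned in world space); it is then
#' center-cropped or padded with -1000 HU (air) to the target shape.
#'
#' @param vol an [image_volume()].
#' @param target_shape integer length-3 `(slices, rows, cols)`.
#' @param target_spacing numeric length-3, defaults to the input spacing.
#' @return an [image_volume()] with exactly the target shape.
#' @export
crop_resize <- function(vol, target_shape, target_spacing = vol$spacing) {
  stopifnot(is_volume(vol))
  target_shape <- as.integer(target_shape)
  if (any(target_shape <= 0) || any(target_spacing <= 0))
    stop("target shape and spacing must be positive")
  d <- dim(vol$data)
  arr <- vol$data
  spacing <- vol$spacing
  if (max(abs(target_spacing - spacing)) > 1e-9) {
    newd <- pmax(1L, as.integer(round(d * spacing / target_spacing)))
    ctr <- vol$origin + (d - 1) / 2 * spacing
    neworigin <- ctr - (newd - 1) / 2 * target_spacing
    arr <- resample_affine_cpp(arr, as.integer(d), spacing, vol$origin,
                               newd, as.numeric(target_spacing), neworigin,
                               diag(3), rep(0, 3), rep(0, 3), -1000)
    d <- newd
    spacing <- as.numeric(target_spacing)
    vol <- image_volume(arr, spacing, neworigin, vol$frame)
  }
  out <- array(-1000, target_shape)
  # center-anchored copy window
  lo_in <- pmax(0L, (d - target_shape) %/% 2L)
  lo_out <- pmax(0L, (target_shape - d) %/% 2L)
  len <- pmin(d - lo_in, target_shape - lo_out)
  out[lo_out[1] + seq_len(len[1]), lo_out[2] + seq_len(len[2]),
      lo_out[3] + seq_len(len[3])] <-
    vol$data[lo_in[1] + seq_len(len[1]), lo_in[2] + seq_len(len[2]),
             lo_in[3] + seq_len(len[3])]
  neworigin <- vol$origin + (lo_in - lo_out) * spacing
  image_volume(out, spacing, neworigin, vol$frame)
}

# --- similarity metrics -----------------------------------------------------

mutual_information <- function(a, b, nbins = 32) {
  ra <- range(a)
  rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(0)
  ia <- pmin(pmax(floor((a - ra[1]) / diff(ra) * nbins) + 1L, 1L), nbins)
  ib <- pmin(pmax(floor((b - rb[1]) / diff(rb) * nbins) + 1L, 1L), nbins)
  joint <- tabulate((ia - 1L) * nbins + ib, nbins * nbins) / length(a)
  pa <- tabulate(ia, nbins) / length(a)
  pb <- tabulate(ib, nbins) / length(b)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ent(pa) + ent(pb) - ent(joint)
}

euler_rotation <- function(deg) {
  a <- deg * pi / 180
  # rotations about slice, row, col axes (applied col %*% row %*% slice)
  Rz <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  Rr <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  Rc <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  Rc %*% Rr %*% Rz
}

rigid_resample <- function(moving, fixed, params, background = -1000) {
  R <- euler_rotation(params[4:6])
  ctr <- fixed$origin + (dim(fixed$data) - 1) / 2 * fixed$spacing
  arr <- resample_affine_cpp(moving$data, dim(moving$data), moving$spacing,
                             moving$origin, dim(fixed$data), fixed$spacing,
                             fixed$origin, R, params[1:3], ctr, background)
  image_volume(arr, fixed$spacing, fixed$origin, moving$frame)
}

#' 3D rigid registration (6 parameters)
#'
#' Aligns `moving` (planning CT) onto the grid of `fixed` (CBCT, the
#' reference sequence) by maximizing an intensity similarity metric over
#' 3 translations (mm) and 3 rotations (degrees) about the fixed-volume
#' center. Mutual information is the default metric since the CBCT/CT
#' intensity relationship is not the identity; optimization is
#' derivative-free (Nelder-Mead) over a two-level resolution pyramid.
#'
#' @param moving,fixed [image_volume()]s; `fixed` is the reference.
#' @param metric `"mi"` (default) or `"ssd"`.
#' @param nbins histogram bins for mutual information.
#' @param maxit iterations per pyramid level.
#' @return list with `params` (named length-6: translations mm,
#'   rotations deg), `resampled` (moving on the fixed grid) and `metric`
#'   (final similarity).
#' @export
rigid_register <- function(moving, fixed, metric = c("mi", "ssd"),
                           nbins = 32, maxit = 300) {
  stopifnot(is_volume(moving), is_volume(fixed))
  metric <- match.arg(metric)
  # require world-extent overlap
  ext <- function(v) rbind(v$origin, v$origin + (dim(v$data) - 1) * v$spacing)
  em <- ext(moving); ef <- ext(fixed)
  if (any(em[2, ] < ef[1, ]) || any(ef[2, ] < em[1, ]))
    stop("volumes do not overlap in world space")

  score <- function(params, mov, fix) {
    res <- rigid_resample(mov, fix, params)
    if (metric == "mi") -mutual_information(res$data, fix$data, nbins)
    else mean((res$data - fix$data)^2)
  }
  shrink <- function(v) {
    d <- dim(v$data)
    if (any(d < 8)) return(v)
    sm <- gauss_blur3_cpp(v$data, as.integer(d), rep(0.8, 3))
    newd <- pmax(4L, d %/% 2L)
    arr <- resample_affine_cpp(sm, as.integer(d), v$spacing, v$origin, newd,
                               v$spacing * d / newd,
                               v$origin, diag(3), rep(0, 3), rep(0, 3), -1000)
    image_volume(arr, v$spacing * d / newd, v$origin, v$frame)
  }
  # initialize translation from the body centers of mass (robust to the
  # local optima of a derivative-free intensity search)
  com <- function(v) {
    w <- pmax(v$data + 1000, 0) * (v$data > -400)
    idx <- which(w > 0, arr.ind = TRUE)
    ww <- w[w > 0]
    ctr_idx <- colSums(idx * ww) / sum(ww) - 1
    v$origin + ctr_idx * v$spacing
  }
  p <- c(com(moving) - com(fixed), 0, 0, 0)
  lvl <- list(list(mov = shrink(moving), fix = shrink(fixed)),
              list(mov = moving, fix = fixed))
  # coarse per-axis rotation sweep: derivative-free search alone stalls
  # on the plateaus of a histogram metric
  for (ax in 4:6) {
    cand <- seq(-12, 12, by = 1.5)
    vals <- vapply(cand, function(a) {
      q <- p
      q[ax] <- a
      score(q, lvl[[1]]$mov, lvl[[1]]$fix)
    }, numeric(1))
    p[ax] <- cand[which.min(vals)]
  }
  for (L in lvl) {
    opt <- stats::optim(p, score, mov = L$mov, fix = L$fix,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit,
                                       parscale = c(rep(4, 3), rep(3, 3))))
    p <- opt$par
  }
  names(p) <- c("t_slice", "t_row", "t_col", "rot_slice", "rot_row", "rot_col")
  list(params = p, resampled = rigid_resample(moving, fixed, p),
       metric = if (metric == "mi") -opt$value else opt$value)
}

write_rigid_sidecar <- function(params, path) {
  writeLines(sprintf("%s: %.8g", names(params), params), path)
  invisible(path)
}

#' Multiresolution B-spline deformable registration
#'
#' Estimates a smooth displacement field mapping the (rigidly aligned)
#' planning CT onto the CBCT by optimizing cubic B-spline control-point
#' displacements with L-BFGS-B over a coarse-to-fine pyramid (>= 2
#' levels). The data term is mean squared intensity difference with
#' analytic gradients; a curvature-style penalty on control points keeps
#' the field smooth. Returns the deformed CT (the evaluation reference,
#' dCT) and the estimated field in voxel units (`dct(p) = moving(p + f(p))`).
#'
#' @param moving_ct,fixed_cbct [image_volume()]s on the same grid.
#' @param control_spacing control-point spacing in voxels at the finest
#'   level (per axis, recycled).
#' @param levels number of resolution levels (>= 2).
#' @param maxit L-BFGS-B iterations per level.
#' @param lambda weight of the control-point smoothness penalty.
#' @return list with `dct` ([image_volume()]) and `field`
#'   (slices x rows x cols x 3).
#' @export
deformable_register <- function(moving_ct, fixed_cbct, control_spacing = 4,
                                levels = 2, maxit = 40, lambda = 1e-7) {
  stop_if_grid_mismatch(moving_ct, fixed_cbct)
  stopifnot(levels >= 2)
  d <- dim(moving_ct$data)
  csp <- rep(control_spacing, length.out = 3)
  base_field <- array(0, c(d, 3))

  for (lev in seq(levels, 1)) {
    blur <- if (lev > 1) rep(0.7 * lev, 3) else c(0, 0, 0)
    mov <- if (lev > 1)
      gauss_blur3_cpp(moving_ct$data, as.integer(d), blur) else moving_ct$data
    fix <- if (lev > 1)
      gauss_blur3_cpp(fixed_cbct$data, as.integer(d), blur) else
        fixed_cbct$data
    sp <- pmax(csp * lev, 2)
    ncp <- vapply(1:3, function(a) bspline_ncoef_cpp(d[a], sp[a]), 0L)
    coef0 <- numeric(prod(ncp) * 3)
    # spatial gradient of the moving image (voxel units)
    gr <- spatial_gradient3(mov, d)
    nvox <- prod(d)
    obj <- function(cf) {
      field <- bspline_eval_cpp(cf, ncp, as.integer(d), sp) + base_field
      w <- warp3d_cpp(mov, field, as.integer(d), 0L)
      r <- w - fix
      val <- mean(r^2) + lambda * sum(cf^2)
      gfield <- array(0, c(d, 3))
      for (comp in 1:3) {
        gi <- warp3d_cpp(gr[[comp]], field, as.integer(d), 0L)
        gfield[, , , comp] <- 2 * r * gi / nvox
      }
      gcoef <- bspline_adjoint_cpp(gfield, ncp, as.integer(d), sp) +
        2 * lambda * cf
      attr(val, "gradient") <- as.numeric(gcoef)
      val
    }
    env <- new.env()
    fn <- function(cf) {
      v <- obj(cf)
      env$grad <- attr(v, "gradient")
      as.numeric(v)
    }
    gfun <- function(cf) env$grad
    opt <- stats::optim(coef0, fn, gfun, method = "L-BFGS-B",
                        control = list(maxit = maxit))
    if (!opt$convergence %in% c(0, 1))
      stop(sprintf("deformable registration failed to converge (code %d, metric %.6g)",
                   opt$convergence, opt$value))
    base_field <- base_field +
      bspline_eval_cpp(opt$par, ncp, as.integer(d), sp)
  }
  dct <- warp3d_cpp(moving_ct$data, base_field, as.integer(d), 0L)
  list(dct = image_volume(array(dct, d), moving_ct$spacing, moving_ct$origin,
                          "dct"),
       field = base_field)
}

spatial_gradient3 <- function(vol, d) {
  g <- vector("list", 3)
  for (a in 1:3) {
    gp <- array(0, d)
    n <- d[a]
    idx_hi <- c(2:n, n)
    idx_lo <- c(1, 1:(n - 1))
    if (a == 1) gp <- (vol[idx_hi, , , drop = FALSE] -
                         vol[idx_lo, , , drop = FALSE]) / 2
    if (a == 2) gp <- (vol[, idx_hi, , drop = FALSE] -
                         vol[, idx_lo, , drop = FALSE]) / 2
    if (a == 3) gp <- (vol[, , idx_hi, drop = FALSE] -
                         vol[, , idx_lo, drop = FALSE]) / 2
    g[[a]] <- array(gp, d)
  }
  g
}
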