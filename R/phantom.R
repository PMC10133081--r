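# Synthetic thoracic phantom: parametric-analytic anatomy (ellipsoids,
# tubes, blocks) with seeded per-patient jitter, a smooth random
# inter-scan deformation, CBCT-style degradation, and a toy dose grid.
# Everything is deterministic given its spec's seed.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Parameters of the analytic thoracic phantom. All geometry is in mm,
#' relative to the grid center; HU values per tissue class are assigned
#' exactly (piecewise-constant planning CT). The seed drives a small
#' per-patient jitter of organ centers and sizes so that repeated calls
#' emulate different patients.
#'
#' @param shape grid shape `(slices, rows, cols)`.
#' @param spacing voxel spacing mm `(slice, row, col)`.
#' @param body_semi in-plane semi-axes (row, col) of the body ellipse, mm.
#' @param lung_semi lung ellipsoid semi-axes (slice, row, col), mm.
#' @param lung_center_offset lung center offset (slice, row, +/-col), mm.
#' @param heart_radius,heart_center heart sphere radius / center offset, mm.
#' @param eso_radius,eso_center esophagus tube radius / in-plane center, mm.
#' @param cord_radius,cord_center spinal-cord tube radius / center, mm.
#' @param bone_rows,bone_cols vertebral block extents (mm, relative center).
#' @param ctv_radius CTV tube radius around the esophagus, mm (> 0).
#' @param ctv_halflen CTV half-length along the slice axis, mm.
#' @param ptv_margin isotropic CTV-to-PTV expansion, mm.
#' @param hu named HU per tissue class (air, soft, lung, heart, esophagus,
#'   cord, bone, tumor); lung defaults to -900 HU.
#' @param jitter_mm,jitter_scale magnitude of the seeded per-patient
#'   center jitter (mm) and relative size jitter.
#' @param seed integer random seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(16L, 64L, 64L), spacing = c(4, 4, 4),
                         body_semi = c(105, 118),
                         lung_semi = c(28, 72, 40),
                         lung_center_offset = c(0, -8, 62),
                         heart_radius = 32, heart_center = c(0, 18, -14),
                         eso_radius = 8, eso_center = c(28, 2),
                         cord_radius = 7, cord_center = c(64, 0),
                         bone_rows = c(76, 108), bone_cols = c(-20, 20),
                         ctv_radius = 14, ctv_halflen = 20, ptv_margin = 8,
                         hu = c(air = -1000, soft = 40, lung = -900,
                                heart = 45, esophagus = 50, cord = 35,
                                bone = 700, tumor = 55),
                         jitter_mm = 4, jitter_scale = 0.06, seed = 1L) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               body_semi = body_semi, lung_semi = lung_semi,
               lung_center_offset = lung_center_offset,
               heart_radius = heart_radius, heart_center = heart_center,
               eso_radius = eso_radius, eso_center = eso_center,
               cord_radius = cord_radius, cord_center = cord_center,
               bone_rows = bone_rows, bone_cols = bone_cols,
               ctv_radius = ctv_radius, ctv_halflen = ctv_halflen,
               ptv_margin = ptv_margin, hu = hu,
               jitter_mm = jitter_mm, jitter_scale = jitter_scale,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(s) {
  pos <- c(s$body_semi, s$lung_semi, s$heart_radius, s$eso_radius,
           s$cord_radius)
  if (any(pos <= 0)) stop("all semi-axes and radii must be positive")
  if (s$ctv_radius <= 0) stop("CTV radius must be positive (empty CTV)")
  if (any(s$hu < -1024 | s$hu > 3000)) stop("organ HU outside [-1024, 3000]")
  if (any(s$shape < 4)) stop("grid too small")
  invisible(s)
}

#' CBCT degradation specification
#'
#' Amplitudes of the artifacts applied to the treatment-day CT to emulate
#' CBCT: a smooth low-frequency shading (bias) field, angularly periodic
#' streaks, a lung-restricted HU offset (scatter raises apparent lung HU),
#' and additive Gaussian noise.
#'
#' @param shading_amp bias-field amplitude, HU (max |bias|).
#' @param shading_scale bias-field spatial scale, mm.
#' @param streak_amp streak amplitude, HU.
#' @param streak_freq angular frequency (cycles per revolution).
#' @param streak_count number of streak components.
#' @param lung_offset HU offset added inside the lung, HU (signed).
#' @param noise_sd additive Gaussian noise standard deviation, HU.
#' @param seed integer random seed.
#' @export
artifact_spec <- function(shading_amp = 60, shading_scale = 80,
                          streak_amp = 40, streak_freq = 12,
                          streak_count = 4, lung_offset = 150,
                          noise_sd = 20, seed = 1L) {
  if (any(c(shading_amp, streak_amp, noise_sd) < 0))
    stop("artifact amplitudes and noise sd must be >= 0")
  structure(list(shading_amp = shading_amp, shading_scale = shading_scale,
                 streak_amp = streak_amp, streak_freq = streak_freq,
                 streak_count = as.integer(streak_count),
                 lung_offset = lung_offset, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "artifact_spec")
}

#' Inter-scan deformation specification
#'
#' The treatment-day anatomy is the planning anatomy warped by a random
#' smooth displacement field: i.i.d. Gaussian vectors smoothed by a
#' Gaussian kernel and rescaled so the maximum per-voxel Euclidean norm
#' equals `magnitude` (voxel units).
#'
#' @param magnitude maximum displacement, voxels (>= 0).
#' @param smoothness std of the smoothing kernel, voxels (> 0).
#' @param seed integer random seed.
#' @export
deform_spec <- function(magnitude = 2.5, smoothness = 6, seed = 1L) {
  if (magnitude < 0) stop("magnitude must be >= 0")
  if (smoothness <= 0) stop("smoothness must be > 0")
  structure(list(magnitude = magnitude, smoothness = smoothness,
                 seed = as.integer(seed)), class = "deform_spec")
}

# voxel-center coordinate grids in mm relative to the volume center
grid_mm <- function(shape, spacing) {
  lapply(1:3, function(a)
    (seq_len(shape[a]) - 1 - (shape[a] - 1) / 2) * spacing[a])
}

#' Generate a planning-CT phantom and its structure set
#'
#' Paints tissue classes in anatomical order (body, lungs, heart,
#' esophagus, cord, vertebral bone, tumor) onto the grid, then derives
#' ROI masks. The CTV is a tube around the esophagus; the PTV is its
#' isotropic expansion clipped to the body.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `ct` ([image_volume()]) and
#'   `rois` ([structure_set()]).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  validate_phantom_spec(spec)
  s <- with_seed(spec$seed, jitter_spec(spec))
  d <- s$shape
  sp <- s$spacing
  g <- grid_mm(d, sp)
  z <- array(rep(g[[1]], times = prod(d[2:3])), d)
  r <- array(rep(rep(g[[2]], each = d[1]), times = d[3]), d)
  cc <- array(rep(g[[3]], each = prod(d[1:2])), d)
  half <- (d - 1) / 2 * sp

  # organs may be truncated by the scanned slab in z (as in a real
  # thoracic field of view); in-plane overflow is a geometry error
  check_fit <- function(name, zmax, rmax, cmax) {
    if (rmax > half[2] + sp[2] / 2 || cmax > half[3] + sp[3] / 2)
      stop(sprintf("organ geometry exceeds the grid: %s", name))
  }
  check_fit("body", 0, s$body_semi[1], s$body_semi[2])

  body <- (r / s$body_semi[1])^2 + (cc / s$body_semi[2])^2 <= 1

  lung_mask <- function(side) {
    ctr <- s$lung_center_offset
    ctr[3] <- ctr[3] * side
    check_fit(if (side < 0) "left lung" else "right lung",
              abs(ctr[1]) + s$lung_semi[1], abs(ctr[2]) + s$lung_semi[2],
              abs(ctr[3]) + s$lung_semi[3])
    ((z - ctr[1]) / s$lung_semi[1])^2 + ((r - ctr[2]) / s$lung_semi[2])^2 +
      ((cc - ctr[3]) / s$lung_semi[3])^2 <= 1
  }
  # "left" is the negative-column side of the grid
  lung_l <- lung_mask(-1) & body
  lung_r <- lung_mask(+1) & body

  check_fit("heart", abs(s$heart_center[1]) + s$heart_radius,
            abs(s$heart_center[2]) + s$heart_radius,
            abs(s$heart_center[3]) + s$heart_radius)
  heart <- (z - s$heart_center[1])^2 + (r - s$heart_center[2])^2 +
    (cc - s$heart_center[3])^2 <= s$heart_radius^2
  heart <- heart & body

  check_fit("esophagus", 0, abs(s$eso_center[1]) + s$eso_radius,
            abs(s$eso_center[2]) + s$eso_radius)
  eso <- (r - s$eso_center[1])^2 + (cc - s$eso_center[2])^2 <= s$eso_radius^2
  check_fit("spinal cord", 0, abs(s$cord_center[1]) + s$cord_radius,
            abs(s$cord_center[2]) + s$cord_radius)
  cord <- (r - s$cord_center[1])^2 + (cc - s$cord_center[2])^2 <=
    s$cord_radius^2
  check_fit("vertebral bone", 0, max(abs(s$bone_rows)), max(abs(s$bone_cols)))
  bone <- r >= s$bone_rows[1] & r <= s$bone_rows[2] &
    cc >= s$bone_cols[1] & cc <= s$bone_cols[2] & body

  ctv <- (r - s$eso_center[1])^2 + (cc - s$eso_center[2])^2 <=
    s$ctv_radius^2 & abs(z) <= s$ctv_halflen
  ctv <- ctv & body
  if (!any(ctv)) stop("organ geometry exceeds the grid: CTV (empty)")
  # Euclidean expansion of the CTV tube: same axis, enlarged radius/length
  ptv <- (r - s$eso_center[1])^2 + (cc - s$eso_center[2])^2 <=
    (s$ctv_radius + s$ptv_margin)^2 & abs(z) <= s$ctv_halflen + s$ptv_margin
  ptv <- (ptv | ctv) & body

  hu <- s$hu
  vol <- array(hu[["air"]], d)
  vol[body] <- hu[["soft"]]
  vol[lung_l | lung_r] <- hu[["lung"]]
  vol[heart] <- hu[["heart"]]
  vol[eso & body] <- hu[["esophagus"]]
  vol[cord & body] <- hu[["cord"]]
  vol[bone] <- hu[["bone"]]
  vol[ctv] <- hu[["tumor"]]

  # organ masks exclude voxels later overwritten by another tissue
  lab_keep <- function(m, over) m & !over
  lung_l2 <- lab_keep(lung_l, heart | (eso & body) | (cord & body) | bone | ctv)
  lung_r2 <- lab_keep(lung_r, heart | (eso & body) | (cord & body) | bone | ctv)
  heart2 <- lab_keep(heart, (eso & body) | (cord & body) | bone | ctv)
  eso2 <- lab_keep(eso & body, (cord & body) | bone | ctv)
  cord2 <- lab_keep(cord & body, bone | ctv)
  bone2 <- lab_keep(bone, ctv)

  rois <- structure_set(list(
    body = body, lung_left = lung_l2, lung_right = lung_r2,
    lung_total = lung_l2 | lung_r2, heart = heart2, cord = cord2,
    esophagus = eso2, bone = bone2, ctv = ctv, ptv = ptv))
  origin <- -half
  list(ct = image_volume(vol, spacing = sp, origin = origin,
                         frame = "planning"),
       rois = rois)
}

jitter_spec <- function(spec) {
  s <- spec
  j <- function(x) x + stats::runif(length(x), -s$jitter_mm, s$jitter_mm)
  sc <- function(x) x * stats::runif(length(x), 1 - s$jitter_scale,
                                     1 + s$jitter_scale)
  s$body_semi <- sc(s$body_semi)
  s$lung_semi <- sc(s$lung_semi)
  s$lung_center_offset <- s$lung_center_offset +
    stats::runif(3, -s$jitter_mm, s$jitter_mm) * c(0, 1, 0)
  s$heart_radius <- sc(s$heart_radius)
  s$heart_center <- j(s$heart_center)
  s$eso_center <- j(s$eso_center)
  s$cord_center <- j(s$cord_center)
  s$ctv_radius <- sc(s$ctv_radius)
  s
}

#' Random smooth displacement field
#'
#' i.i.d. Gaussian component fields smoothed by a Gaussian kernel and
#' rescaled so the maximum per-voxel Euclidean norm equals `magnitude`.
#'
#' @param shape grid shape `(slices, rows, cols)`.
#' @param d a [deform_spec()].
#' @return array `(slices, rows, cols, 3)`, voxel units.
#' @export
random_smooth_field <- function(shape, d) {
  field <- with_seed(d$seed, {
    f <- array(stats::rnorm(prod(shape) * 3), c(shape, 3))
    for (comp in 1:3)
      f[, , , comp] <- gauss_blur3_cpp(f[, , , comp], as.integer(shape),
                                       rep(d$smoothness, 3))
    f
  })
  nrm <- sqrt(field[, , , 1]^2 + field[, , , 2]^2 + field[, , , 3]^2)
  mx <- max(nrm)
  if (mx > 0) field <- field * (d$magnitude / mx)
  field
}

#' Deform the planning anatomy to a treatment-day anatomy
#'
#' Warps the planning CT (trilinear) and its ROI masks (nearest neighbor)
#' by a random smooth field and returns the ground-truth field, so that
#' downstream registration-recovery checks are possible. The field `f` is
#' a pull-back map: `day(p) = planning(p + f(p))`.
#'
#' @param planning planning-CT [image_volume()].
#' @param rois [structure_set()] on the same grid.
#' @param d a [deform_spec()].
#' @return list with `ct` (day CT), `rois` (warped masks) and
#'   `field` (slices x rows x cols x 3 array, voxel units).
#' @export
make_day_anatomy <- function(planning, rois, d = deform_spec()) {
  if (!identical(dim(planning$data), dim(rois[[1]])))
    stop("planning volume and ROI masks are not on the same grid")
  shape <- dim(planning$data)
  field <- random_smooth_field(shape, d)
  day <- warp3d_cpp(planning$data, field, as.integer(shape), 0L)
  wmask <- lapply(unclass(rois), function(m) {
    w <- warp3d_cpp(m + 0, field, as.integer(shape), 1L)
    array(w > 0.5, shape)
  })
  list(ct = image_volume(day, planning$spacing, planning$origin, "day"),
       rois = structure_set(wmask), field = field)
}

#' Degrade a treatment-day CT to an emulated CBCT
#'
#' Adds, in order: a smooth low-frequency shading field, angularly
#' periodic streaks, a lung-restricted HU offset, and Gaussian noise;
#' the result is clipped to `[-1024, 3000]` HU. All random draws are
#' taken regardless of amplitude so that the same seed produces the same
#' underlying patterns at any amplitude setting.
#'
#' @param day_ct [image_volume()] in HU.
#' @param a an [artifact_spec()].
#' @param lung_mask optional logical array; when `NULL` the lung is
#'   derived by thresholding HU in `[-950, -600]`.
#' @return CBCT [image_volume()].
#' @export
degrade_to_cbct <- function(day_ct, a = artifact_spec(), lung_mask = NULL) {
  d <- dim(day_ct$data)
  sp <- day_ct$spacing
  out <- with_seed(a$seed, {
    bias_raw <- array(stats::rnorm(prod(d)), d)
    sig <- pmax(a$shading_scale / sp, 1e-6)
    bias_raw <- gauss_blur3_cpp(bias_raw, as.integer(d), sig)
    bias <- if (max(abs(bias_raw)) > 0)
      bias_raw / max(abs(bias_raw)) * a$shading_amp else bias_raw * 0

    g <- grid_mm(d, sp)
    theta <- atan2(rep(rep(g[[2]], each = d[1]), times = d[3]),
                   rep(g[[3]], each = prod(d[1:2])))
    n <- max(1L, a$streak_count)
    phases <- stats::runif(n, 0, 2 * pi)
    freqs <- round(a$streak_freq * stats::runif(n, 0.75, 1.25))
    streak_v <- rowMeans(vapply(seq_len(n), function(i)
      sin(freqs[i] * theta + phases[i]), numeric(length(theta))))
    streak <- array(a$streak_amp * streak_v, d)

    noise <- array(stats::rnorm(prod(d), sd = a$noise_sd), d)

    if (is.null(lung_mask))
      lung_mask <- day_ct$data > -950 & day_ct$data < -600
    cbct <- day_ct$data + bias + streak + a$lung_offset * lung_mask + noise
    pmin(pmax(cbct, -1024), 3000)
  })
  image_volume(array(out, d), sp, day_ct$origin, "cbct")
}

#' Toy dose grid from beam profiles
#'
#' The dose is the sum of `n_beams` anisotropic Gaussian beam profiles
#' whose axes pass through the PTV centroid at evenly spaced in-plane
#' gantry angles, attenuated exponentially with radiological depth, and
#' scaled so the PTV median dose equals the prescription. When a density
#' image is supplied (HU), the radiological depth is computed through the
#' relative electron density `(HU + 1000) / 1000`, so dose grids computed
#' on different images of the same anatomy differ — which is what the
#' gamma comparison measures. Without a density image, unit density is
#' used.
#'
#' @param rois [structure_set()] with a nonempty `ptv` mask.
#' @param prescription_gy prescription dose, Gy (default 50.4, i.e.
#'   50.4 Gy in 28 fractions).
#' @param n_beams number of beams (4-5 typical).
#' @param density optional [image_volume()] in HU used for attenuation.
#' @param spacing voxel spacing, taken from `density` when given.
#' @param mu effective linear attenuation per mm of water-equivalent path.
#' @param sigma_margin_mm widening of the beam Gaussian beyond the PTV.
#' @param scale fixed monitor-unit scaling (Gy per unit profile). By
#'   default the grid is scaled so the PTV median equals the
#'   prescription; when the same plan is recomputed on another image of
#'   the same anatomy, pass the reference grid's `dose_scale` attribute
#'   instead, so that attenuation differences show up as absolute dose
#'   differences (as they do when a fixed plan is recalculated).
#' @return dose [image_volume()] (frame `"dose"`), Gy, with attribute
#'   `dose_scale`.
#' @export
make_dose <- function(rois, prescription_gy = 50.4, n_beams = 5L,
                      density = NULL, spacing = c(4, 4, 4),
                      mu = 0.004, sigma_margin_mm = 10, scale = NULL) {
  if (is.null(rois$ptv) || !any(rois$ptv)) stop("PTV mask is empty")
  if (prescription_gy <= 0) stop("prescription must be > 0")
  n_beams <- as.integer(n_beams)
  if (n_beams < 1) stop("n_beams must be >= 1")
  d <- dim(rois$ptv)
  if (!is.null(density)) {
    if (!identical(dim(density$data), d))
      stop("density grid does not match ROI grid")
    spacing <- density$spacing
  }
  g <- grid_mm(d, spacing)
  idx <- which(rois$ptv, arr.ind = TRUE)
  ctr <- c(mean(g[[1]][idx[, 1]]), mean(g[[2]][idx[, 2]]),
           mean(g[[3]][idx[, 3]]))
  # beam width from PTV in-plane extent; length Gaussian along slices
  rext <- max(abs(g[[2]][idx[, 2]] - ctr[2]), abs(g[[3]][idx[, 3]] - ctr[3]))
  zext <- max(abs(g[[1]][idx[, 1]] - ctr[1]))
  sig_p <- rext + sigma_margin_mm
  sig_z <- zext + sigma_margin_mm

  rr <- g[[2]]
  cc <- g[[3]]
  rmat <- matrix(rep(rr, times = d[3]), d[2], d[3])
  cmat <- matrix(rep(cc, each = d[2]), d[2], d[3])
  zgauss <- exp(-(g[[1]] - ctr[1])^2 / (2 * sig_z^2))

  angles <- (seq_len(n_beams) - 1) * 2 * pi / n_beams
  dose <- array(0, d)
  for (k in seq_len(d[1])) {
    dens_sl <- if (is.null(density)) matrix(1, d[2], d[3]) else
      pmax((density$data[k, , ] + 1000) / 1000, 0)
    acc <- matrix(0, d[2], d[3])
    for (phi in angles) {
      dirr <- cos(phi)
      dirc <- sin(phi)
      depth <- beam_depth_cpp(dens_sl, dirr, dirc, spacing[2], spacing[3],
                              min(spacing[2:3]) / 2)
      # perpendicular distance to the beam axis through the PTV centroid
      perp <- abs(-(rmat - ctr[2]) * dirc + (cmat - ctr[3]) * dirr)
      acc <- acc + exp(-mu * depth) * exp(-perp^2 / (2 * sig_p^2))
    }
    dose[k, , ] <- acc * zgauss[k]
  }
  if (is.null(scale)) scale <- prescription_gy / stats::median(dose[rois$ptv])
  dose <- dose * scale
  origin <- -(d - 1) / 2 * spacing
  out <- image_volume(dose, spacing, origin, "dose")
  attr(out, "dose_scale") <- scale
  out
}

#' Write a complete synthetic dataset to disk
#'
#' Generates `n_train + n_test` phantom patients (planning CT, day CT,
#' CBCT, ROI bitmask labels, toy dose on the day anatomy, and the
#' ground-truth deformation field), writes them as NIfTI under
#' `out_dir/pt###/`, and returns (and writes) a manifest. Identical
#' arguments reproduce bit-identical files.
#'
#' @param n_train,n_test patient counts (>= 0).
#' @param out_dir output directory (created if needed).
#' @param seed master seed; per-patient seeds are derived from it.
#' @param phantom,artifact,deform template specs; their seeds are
#'   replaced by the derived per-patient seeds.
#' @param prescription_gy,n_beams dose settings, see [make_dose()].
#' @return manifest as a data.frame (invisibly also written to
#'   `manifest.txt` as flat key-value lines).
#' @export
make_dataset <- function(n_train, n_test, out_dir, seed = 1L,
                         phantom = phantom_spec(), artifact = artifact_spec(),
                         deform = deform_spec(), prescription_gy = 50.4,
                         n_beams = 5L) {
  stopifnot(n_train >= 0, n_test >= 0)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  n <- n_train + n_test
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pseed <- derive_seed(seed, i)
    pdir <- file.path(out_dir, sprintf("pt%03d", i))
    dir.create(pdir, showWarnings = FALSE)
    ph <- phantom; ph$seed <- pseed
    ar <- artifact; ar$seed <- derive_seed(pseed, 1L)
    de <- deform; de$seed <- derive_seed(pseed, 2L)
    p <- make_phantom(ph)
    day <- make_day_anatomy(p$ct, p$rois, de)
    cbct <- degrade_to_cbct(day$ct, ar, lung_mask = day$rois$lung_total)
    dose <- make_dose(day$rois, prescription_gy, n_beams, density = day$ct,
                      spacing = ph$spacing)
    write_volume(p$ct, file.path(pdir, "planning.nii.gz"))
    write_volume(day$ct, file.path(pdir, "day.nii.gz"))
    write_volume(cbct, file.path(pdir, "cbct.nii.gz"))
    lab <- encode_rois(day$rois)
    write_volume(image_volume(lab + 0, ph$spacing, p$ct$origin, ""),
                 file.path(pdir, "rois.nii.gz"))
    write_roi_sidecar(file.path(pdir, "roi_table.txt"))
    write_volume(dose, file.path(pdir, "dose.nii.gz"))
    write_field(day$field, ph$spacing, file.path(pdir, "field.nii.gz"))
    rows[[i]] <- data.frame(
      patient = sprintf("pt%03d", i), split = if (i <= n_train) "train"
      else "test", seed = pseed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  lines <- c(sprintf("n_train: %d", n_train), sprintf("n_test: %d", n_test),
             sprintf("seed: %d", seed),
             sprintf("patient_%s: split=%s seed=%d", manifest$patient,
                     manifest$split, manifest$seed))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  invisible(manifest)
}

derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483647)
}
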