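# Dose comparison: global (absolute) gamma-index maps and passing rates,
# DVH curves, and scalar DVH parameters (D98, Vx, mean/max doses).

#' Gamma criteria
#'
#' @param dose_tol dose tolerance as % of the global normalization dose.
#' @param dta distance-to-agreement, mm.
#' @param cutoff low-dose cutoff as % of the normalization dose
#'   (default 10); reference points below it are excluded.
#' @export
gamma_criteria <- function(dose_tol, dta, cutoff = 10) {
  if (dose_tol <= 0 || dta <= 0) stop("dose tolerance and DTA must be > 0")
  if (cutoff < 0 || cutoff >= 100) stop("cutoff must be in [0, 100)")
  structure(list(dose_tol = dose_tol, dta = dta, cutoff = cutoff),
            class = "gamma_criteria")
}

#' Global gamma-index map and passing rate
#'
#' For each reference voxel above the low-dose cutoff,
#' `gamma(r) = min over r' of sqrt(|r - r'|^2 / DTA^2 +
#' (De(r') - Dr(r))^2 / (tol * Dnorm)^2)`, searched within a radius of
#' 3 DTA with sub-voxel refinement by trilinear dose interpolation
#' (candidate step about DTA / `refine_per_dta`). Normalization is
#' global: `Dnorm = max(ref)` (absolute gamma). A point passes when
#' gamma <= 1.
#'
#' @param ref,eval_dose dose [image_volume()]s on the same grid (resample
#'   first if needed).
#' @param criteria a [gamma_criteria()].
#' @param refine_per_dta candidate points per DTA and axis (>= 1).
#' @return list with `gamma` (array, `NA` below cutoff), `pass_rate`
#'   (% of evaluated points with gamma <= 1), `n_evaluated`.
#' @export
gamma_map <- function(ref, eval_dose, criteria = gamma_criteria(3, 3),
                      refine_per_dta = 3) {
  stop_if_grid_mismatch(ref, eval_dose)
  dnorm_gy <- max(ref$data)
  if (dnorm_gy <= 0) stop("reference dose is zero everywhere")
  d <- dim(ref$data)
  refine <- pmax(1L, as.integer(ceiling(refine_per_dta * ref$spacing /
                                          criteria$dta)))
  g <- gamma_map_cpp(ref$data, eval_dose$data, as.integer(d), ref$spacing,
                     criteria$dta, criteria$dose_tol / 100 * dnorm_gy,
                     criteria$cutoff / 100 * dnorm_gy, refine)
  ok <- !is.na(g)
  list(gamma = g, pass_rate = 100 * mean(g[ok] <= 1 + 1e-12),
       n_evaluated = sum(ok))
}

#' Cumulative dose-volume histograms
#'
#' For each ROI, the percentage of its volume receiving at least each
#' dose level; V(0) = 100% and the curve is nonincreasing.
#'
#' @param dose dose [image_volume()] in Gy.
#' @param rois a [structure_set()] on the dose grid.
#' @param bin_width dose bin width, Gy.
#' @return data.frame with `roi`, `dose_gy` (bin edges) and
#'   `volume_pct`; empty ROIs are flagged with `NA` volumes.
#' @export
dvh <- function(dose, rois, bin_width = 0.1) {
  stopifnot(is_volume(dose))
  dmax <- max(dose$data)
  edges <- seq(0, dmax + bin_width, by = bin_width)
  rows <- lapply(names(rois), function(nm) {
    m <- rois[[nm]]
    if (!identical(dim(m), dim(dose$data))) stop("ROI grid mismatch: ", nm)
    v <- dose$data[m]
    if (length(v) == 0)
      return(data.frame(roi = nm, dose_gy = edges, volume_pct = NA_real_))
    vol <- vapply(edges, function(t) 100 * mean(v >= t), numeric(1))
    data.frame(roi = nm, dose_gy = edges, volume_pct = vol)
  })
  do.call(rbind, rows)
}

# Dx: minimum dose received by the "hottest" x% of the ROI, from sorted
# voxel doses (dose exceeded or met by x% of the volume).
dose_at_volume <- function(v, x_pct) {
  s <- sort(v, decreasing = TRUE)
  k <- max(1L, ceiling(x_pct / 100 * length(s)))
  s[k]
}

volume_at_dose <- function(v, d_gy) 100 * mean(v >= d_gy)

#' Scalar DVH parameters
#'
#' PTV D98 (Gy), total-lung V5 and V20 (%), mean lung dose (Gy),
#' spinal-cord Dmax (Gy), heart V30 (%), mean heart dose (Gy). Vx is the
#' percentage of the ROI volume receiving at least x Gy; D98 the dose
#' received by 98% of the PTV.
#'
#' @param dose dose [image_volume()] in Gy.
#' @param rois [structure_set()] with `ptv`, `lung_total`, `cord` and
#'   `heart` masks.
#' @return one-row data.frame.
#' @export
dvh_params <- function(dose, rois) {
  need <- c("ptv", "lung_total", "cord", "heart")
  for (nm in need)
    if (is.null(rois[[nm]]) || !any(rois[[nm]]))
      stop("missing or empty required ROI: ", nm)
  ptv <- dose$data[rois$ptv]
  lung <- dose$data[rois$lung_total]
  cord <- dose$data[rois$cord]
  heart <- dose$data[rois$heart]
  data.frame(ptv_d98 = dose_at_volume(ptv, 98),
             lung_v5 = volume_at_dose(lung, 5),
             lung_v20 = volume_at_dose(lung, 20),
             mld = mean(lung),
             cord_dmax = max(cord),
             heart_v30 = volume_at_dose(heart, 30),
             mhd = mean(heart))
}
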