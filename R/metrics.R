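# Image-quality evaluation: body outline extraction, masked MAE/RMSE/PSNR
# against the dCT reference, per-ROI HU statistics, HU histograms, and
# paired Wilcoxon signed-rank comparison.

PSNR_PEAK <- 3000  # width of the HU clip window; convention stated in reports

#' Extract the patient outline (body mask)
#'
#' Threshold at -400 HU, keep the largest 6-connected component, and
#' fill holes enclosed within each axial slice (so the lungs belong to
#' the body even when they reach the first or last slice of the scanned
#' slab, as they do in a thoracic field of view).
#'
#' @param vol an [image_volume()] in HU.
#' @param threshold_hu threshold separating patient from air.
#' @return logical array.
#' @export
body_mask <- function(vol, threshold_hu = -400) {
  stopifnot(is_volume(vol))
  d <- dim(vol$data)
  fg <- vol$data > threshold_hu
  if (!any(fg)) stop("body mask is empty (all voxels below threshold)")
  lab <- label3d_cpp(fg, as.integer(d))
  keep <- which.max(tabulate(lab[lab > 0]))
  mask <- array(lab == keep, d)
  for (k in seq_len(d[1])) {
    sl <- mask[k, , ]
    bg <- label3d_cpp(!sl, as.integer(c(d[2], d[3], 1L)))
    dim(bg) <- c(d[2], d[3])
    border <- unique(c(bg[c(1, d[2]), ], bg[, c(1, d[3])]))
    border <- border[border > 0]
    mask[k, , ] <- sl | (bg > 0 & !(bg %in% border))
  }
  mask
}

#' Masked image similarity (MAE, RMSE, PSNR)
#'
#' All three metrics are computed within the supplied mask (typically
#' the patient outline), with the dCT as reference:
#' MAE = mean |t - r|, RMSE = sqrt(mean (t - r)^2),
#' PSNR = 20 log10(PEAK / RMSE) with PEAK = 3000 HU (the width of the
#' clip window); PSNR is `Inf` when RMSE = 0.
#'
#' @param test,ref [image_volume()]s on the same grid.
#' @param mask logical array (nonempty).
#' @return list with `mae`, `rmse`, `psnr`, `n` (mask voxel count).
#' @export
image_similarity <- function(test, ref, mask) {
  stop_if_grid_mismatch(test, ref)
  if (!identical(dim(mask), dim(ref$data))) stop("mask grid mismatch")
  if (!any(mask)) stop("mask is empty")
  dif <- test$data[mask] - ref$data[mask]
  mae <- mean(abs(dif))
  rmse <- sqrt(mean(dif^2))
  psnr <- if (rmse == 0) Inf else 20 * log10(PSNR_PEAK / rmse)
  list(mae = mae, rmse = rmse, psnr = psnr, n = sum(mask))
}

#' Per-ROI HU statistics
#'
#' For each named ROI: mean, standard deviation, median, HU integral
#' (sum over voxels), voxel count, max and min. Empty ROIs are flagged
#' (`empty = TRUE`, statistics `NA`), not reported as zeros.
#'
#' @param vol an [image_volume()].
#' @param rois a [structure_set()] on the volume grid.
#' @return data.frame, one row per ROI.
#' @export
roi_stats <- function(vol, rois) {
  stopifnot(is_volume(vol))
  rows <- lapply(names(rois), function(nm) {
    m <- rois[[nm]]
    if (!identical(dim(m), dim(vol$data))) stop("ROI grid mismatch: ", nm)
    v <- vol$data[m]
    if (length(v) == 0)
      return(data.frame(roi = nm, mean = NA_real_, sd = NA_real_,
                        median = NA_real_, integral = NA_real_, count = 0L,
                        max = NA_real_, min = NA_real_, empty = TRUE))
    data.frame(roi = nm, mean = mean(v), sd = stats::sd(v),
               median = stats::median(v), integral = sum(v),
               count = length(v), max = max(v), min = min(v), empty = FALSE)
  })
  do.call(rbind, rows)
}

#' HU histogram within a mask
#'
#' Fixed-width bins covering `[-1024, 3000]`; counts sum to the mask
#' voxel count.
#'
#' @param vol an [image_volume()].
#' @param mask logical array (nonempty).
#' @param bin_width bin width, HU (default 10).
#' @return data.frame with `center` and `count`.
#' @export
hu_histogram <- function(vol, mask, bin_width = 10) {
  stopifnot(is_volume(vol))
  if (!any(mask)) stop("mask is empty")
  v <- pmin(pmax(vol$data[mask], -1024), 3000)
  breaks <- seq(-1024, 3000 + bin_width, by = bin_width)
  idx <- pmin(findInterval(v, breaks, left.open = FALSE), length(breaks) - 1L)
  counts <- tabulate(idx, length(breaks) - 1L)
  data.frame(center = breaks[-length(breaks)] + bin_width / 2,
             count = counts)
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided paired Wilcoxon signed-rank test with the zero-discard
#' convention for tied pairs. An all-tied input has no signed ranks and
#' is returned as non-significant with `degenerate = TRUE`.
#'
#' @param metric_a,metric_b paired metric vectors, equal length >= 5.
#' @param alpha significance level (default 0.05).
#' @return list with `statistic` (V), `p`, `significant`, `degenerate`,
#'   `n_effective`.
#' @export
paired_compare <- function(metric_a, metric_b, alpha = 0.05) {
  if (length(metric_a) != length(metric_b)) stop("length mismatch")
  if (length(metric_a) < 5) stop("need at least 5 pairs")
  d <- metric_a - metric_b
  nz <- d[d != 0]
  if (length(nz) == 0)
    return(list(statistic = NA_real_, p = 1, significant = FALSE,
                degenerate = TRUE, n_effective = 0L))
  exact <- length(nz) <= 50 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(stats::wilcox.test(metric_a, metric_b,
                                            paired = TRUE, exact = exact))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       significant = wt$p.value < alpha, degenerate = FALSE,
       n_effective = length(nz))
}

#' Per-patient evaluation table
#'
#' One row per ROI and image type, mirroring the layout of tabular HU
#' reports: ROI statistics of the test image alongside the reference.
#' The PSNR peak convention (3000 HU) is recorded in the header comment
#' of the CSV written by [write_eval_csv()].
#'
#' @param patient patient identifier.
#' @param images named list of [image_volume()]s (e.g. dct, cbct, sct).
#' @param rois a [structure_set()].
#' @return data.frame.
#' @export
eval_table <- function(patient, images, rois) {
  rows <- lapply(names(images), function(ty) {
    st <- roi_stats(images[[ty]], rois)
    st$patient <- patient
    st$image <- ty
    st
  })
  do.call(rbind, rows)
}

#' @rdname eval_table
#' @param tab table from [eval_table()].
#' @param path CSV path.
#' @export
write_eval_csv <- function(tab, path) {
  con <- file(path, "w")
  writeLines("# regganct ROI HU statistics; PSNR peak convention: 3000 HU",
             con)
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  invisible(path)
}
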