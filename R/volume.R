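#' @useDynLib regganct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' 3D image volume in Hounsfield units
#'
#' The common currency of the pipeline: a 3D scalar grid indexed
#' `(slice, row, col)` with per-axis voxel spacing and origin in mm.
#' World coordinates are `origin + spacing * (0-based index)` per axis.
#'
#' @param data 3D numeric array, dim `(slices, rows, cols)`.
#' @param spacing numeric length-3, mm per voxel along (slice, row, col).
#' @param origin numeric length-3, mm world position of voxel (1,1,1).
#' @param frame character label: one of `"planning"`, `"day"`, `"cbct"`,
#'   `"sct"`, `"dct"`, `"dose"` or `""`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         frame = "") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)")
  if (!all(is.finite(data))) stop("voxel values must be finite")
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin), frame = frame),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume%s> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              if (nzchar(x$frame)) paste0(" ", x$frame) else "",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  value range [%.1f, %.1f]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "image_volume")

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("volumes are not on the same grid")
  invisible(TRUE)
}

#' Read / write volumes as NIfTI
#'
#' Volumes are stored internally as `(slice, row, col)`; on disk the NIfTI
#' axis order is `(col, row, slice)` so that files open sensibly in
#' standard viewers. Spacing goes to `pixdim`, the origin to the qform.
#'
#' @param vol an [image_volume()] (4D arrays, e.g. displacement fields,
#'   are also accepted and round-tripped).
#' @param path file path, typically ending in `.nii.gz`.
#' @param frame frame label attached on read.
#' @return `read_volume` returns an [image_volume()]; `write_volume`
#'   returns `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  if (is_volume(vol)) {
    arr <- vol$data
    spacing <- vol$spacing
    origin <- vol$origin
  } else stop("write_volume expects an image_volume")
  a <- aperm(arr, c(3, 2, 1))                  # (col,row,slice) on disk
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- spacing[c(3, 2, 1)]
  xf <- rbind(cbind(diag(spacing[c(3, 2, 1)]), origin[c(3, 2, 1)]),
              c(0, 0, 0, 1))
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, frame = "") {
  img <- RNifti::readNifti(path)
  arr <- aperm(as.array(img), c(3, 2, 1))
  sp <- RNifti::pixdim(img)[c(3, 2, 1)]
  xf <- RNifti::xform(img)
  org <- xf[1:3, 4][c(3, 2, 1)]
  image_volume(arr, spacing = sp, origin = as.numeric(org), frame = frame)
}

# 4D field I/O: (slice,row,col,3) voxel-unit displacement
write_field <- function(field, spacing, path) {
  a <- aperm(field, c(3, 2, 1, 4))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(spacing[c(3, 2, 1)], 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_field <- function(path) {
  img <- RNifti::readNifti(path)
  aperm(as.array(img), c(3, 2, 1, 4))
}

#' Named ROI masks on a common grid
#'
#' A structure set is a named list of logical arrays, all on the grid of
#' the volume they annotate. The standard set for the thoracic phantom is
#' body, lung_left, lung_right, lung_total, heart, cord, esophagus, bone,
#' ctv and ptv.
#'
#' @param masks named list of logical 3D arrays with identical dims.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks) {
  stopifnot(is.list(masks), length(masks) > 0, !is.null(names(masks)))
  d <- dim(masks[[1]])
  for (m in masks) stopifnot(is.logical(m), identical(dim(m), d))
  structure(masks, class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d ROIs on %s grid\n", length(x),
              paste(dim(x[[1]]), collapse = " x ")))
  for (nm in names(x))
    cat(sprintf("  %-10s %d voxels\n", nm, sum(x[[nm]])))
  invisible(x)
}

#' Encode / decode ROI masks as a bitmask label volume
#'
#' ROIs overlap (the CTV is inside the PTV, the total lung is the union
#' of left and right), so the on-disk label volume is a bitmask: one bit
#' per ROI, mapped by the sidecar table written next to it.
#'
#' @param rois a [structure_set()].
#' @param lab integer (bitmask) label array as written by the dataset
#'   generator (`rois.nii.gz`).
#' @return `encode_rois` returns an integer array; `decode_rois` a
#'   [structure_set()].
#' @name encode_rois
NULL

roi_bits <- c(body = 1L, lung_left = 2L, lung_right = 4L, lung_total = 8L,
              heart = 16L, cord = 32L, esophagus = 64L, bone = 128L,
              ctv = 256L, ptv = 512L)

#' @rdname encode_rois
#' @export
encode_rois <- function(rois) {
  lab <- array(0L, dim(rois[[1]]))
  for (nm in names(rois)) {
    bit <- roi_bits[[nm]]
    if (is.null(bit)) next
    lab <- lab + bit * rois[[nm]]
  }
  storage.mode(lab) <- "integer"
  lab
}

#' @rdname encode_rois
#' @export
decode_rois <- function(lab) {
  masks <- lapply(roi_bits, function(bit) {
    m <- bitwAnd(as.integer(lab), bit) > 0L
    dim(m) <- dim(lab)
    m
  })
  structure_set(masks)
}

write_roi_sidecar <- function(path) {
  writeLines(c("# ROI bitmask table: name<TAB>bit",
               paste(names(roi_bits), roi_bits, sep = "\t")), path)
  invisible(path)
}
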