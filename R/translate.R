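# 2.5D inference: each axial slice is clip-normalized, translated by the
# generator, denormalized, and the slices are restacked into a volume.
# No inter-slice overlap or smoothing.

pad4 <- function(m) {
  d <- dim(m)
  target <- ((d + 3L) %/% 4L) * 4L
  if (all(target == d)) return(list(m = m, d = d, off = c(0L, 0L)))
  out <- matrix(-1, target[1], target[2])      # normalized air
  off <- (target - d) %/% 2L
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2])] <- m
  list(m = out, d = d, off = off)
}

#' Translate one normalized CBCT slice to a synthetic-CT slice (HU)
#'
#' @param checkpoint a checkpoint list from [load_checkpoint()] (or a
#'   list with element `G`).
#' @param slice2d 2D matrix in HU.
#' @return 2D matrix in HU, bounded by the training clip window.
#' @export
translate_slice <- function(checkpoint, slice2d) {
  if (!is.matrix(slice2d)) stop("slice must be a 2D matrix")
  G <- checkpoint$G
  x <- normalize_slice(slice2d)
  p <- pad4(x)
  out <- generator_forward(G, p$m)
  out <- out[p$off[1] + seq_len(p$d[1]), p$off[2] + seq_len(p$d[2]),
             drop = FALSE]
  denormalize_slice(out)
}

#' Translate a CBCT volume to a synthetic CT
#'
#' Applies the generator slice by slice along the slice axis and stacks
#' the results; grid, spacing and origin are preserved. Slices whose
#' dims are not divisible by 4 are internally padded with normalized air
#' and cropped back. Output HU is bounded by the `[-1000, 2000]` clip
#' window (tanh output, then denormalization).
#'
#' @param checkpoint checkpoint from [load_checkpoint()] (or the list
#'   returned by [train()]).
#' @param cbct an [image_volume()] in HU.
#' @return sCT [image_volume()] (frame `"sct"`).
#' @export
translate_volume <- function(checkpoint, cbct) {
  stopifnot(is_volume(cbct))
  d <- dim(cbct$data)
  out <- array(0, d)
  for (k in seq_len(d[1]))
    out[k, , ] <- translate_slice(checkpoint, cbct$data[k, , ])
  image_volume(out, cbct$spacing, cbct$origin, "sct")
}
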