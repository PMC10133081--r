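# Independent gamma oracle: exhaustive search over ALL voxel positions
# of the eval grid (no search radius), written in plain R.
gamma_oracle <- function(ref, ev, spacing, dta, tol_abs, cutoff_abs) {
  d <- dim(ref)
  w1 <- array((seq_len(d[1]) - 1) * spacing[1], d)
  w2 <- aperm(array((seq_len(d[2]) - 1) * spacing[2], d[c(2, 1, 3)]),
              c(2, 1, 3))
  w3 <- aperm(array((seq_len(d[3]) - 1) * spacing[3], d[c(3, 1, 2)]),
              c(2, 3, 1))
  gam <- array(NA_real_, d)
  tol2 <- tol_abs^2
  dta2 <- dta^2
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    dr <- ref[i, j, k]
    if (dr < cutoff_abs) next
    dist2 <- (w1 - (i - 1) * spacing[1])^2 + (w2 - (j - 1) * spacing[2])^2 +
      (w3 - (k - 1) * spacing[3])^2
    gam[i, j, k] <- sqrt(min(dist2 / dta2 + (ev - dr)^2 / tol2))
  }
  gam
}

# sort-based median oracle (average of middle order statistics)
median_oracle <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
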