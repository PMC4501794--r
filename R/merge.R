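# Two-volume merge. The acquisition protocol records at least two volumes
# per eye and averages them after registration to improve signal; here the
# registration is a per-A-scan axial alignment: for every (y, x) the second
# volume's A-scan is shifted by the integer lag maximising the normalised
# cross-correlation with the first volume's A-scan, then the aligned voxels
# are averaged where both are defined.

#' Merge two co-located OCT volumes by per-A-scan axial alignment
#'
#' For each lateral position the lag `L` in `[-window, window]` maximising
#' the normalised cross-correlation between `vol_a[, y, x]` and the axially
#' shifted `vol_b[, y, x]` is found (ties broken toward the smallest |lag|),
#' and the merged A-scan is the mean of the aligned pair on their overlap
#' and the defined value elsewhere. Metadata are taken from `vol_a`.
#'
#' @param vol_a,vol_b [oct_volume()] objects with identical dimensions and
#'   voxel spacing.
#' @param window maximum absolute lag searched, in pixels (default 20).
#' @return The merged [oct_volume()]; the per-A-scan lag matrix is attached
#'   as attribute `"merge_lags"` (the amount `vol_b` was shifted by).
#' @export
merge_volumes <- function(vol_a, vol_b, window = 20L) {
  stopifnot(inherits(vol_a, "oct_volume"), inherits(vol_b, "oct_volume"))
  if (!identical(dim(vol_a$intensity), dim(vol_b$intensity))) {
    stop_enface("shape_mismatch", "volumes have different grid dimensions.")
  }
  if (vol_a$axial_pitch_um != vol_b$axial_pitch_um ||
      vol_a$lateral_pitch_um != vol_b$lateral_pitch_um) {
    stop_enface("spacing_mismatch", "volumes have different voxel spacing.")
  }
  d <- dim(vol_a$intensity)
  nz <- d[1L]; npix <- d[2L] * d[3L]
  A <- matrix(vol_a$intensity, nz, npix)
  B <- matrix(vol_b$intensity, nz, npix)
  # lags are estimated on lightly smoothed copies (speckle is independent
  # between acquisitions and would otherwise flatten the correlation peak);
  # the merge itself averages the raw voxels
  smooth_vol <- function(v) {
    s <- v
    for (z in seq_len(nz)) s[z, , ] <- gauss_smooth2d(v[z, , ], 1.5)
    gauss_smooth_axial(matrix(s, nz, npix), 1)
  }
  As <- smooth_vol(vol_a$intensity)
  Bs <- smooth_vol(vol_b$intensity)
  lags <- seq(-window, window)
  lags <- lags[order(abs(lags), lags)]  # smallest magnitude first for tie-breaks
  best_lag <- integer(npix)
  best_cc <- rep(-Inf, npix)
  for (L in lags) {
    z <- max(1L, 1L + L):min(nz, nz + L)
    if (length(z) < 2L) next
    a <- As[z, , drop = FALSE]
    b <- Bs[z - L, , drop = FALSE]
    a0 <- sweep(a, 2L, colMeans(a))
    b0 <- sweep(b, 2L, colMeans(b))
    den <- sqrt(colSums(a0 * a0) * colSums(b0 * b0))
    cc <- ifelse(den > 0, colSums(a0 * b0) / den, 0)
    gain <- cc > best_cc
    best_lag[gain] <- L
    best_cc[gain] <- cc[gain]
  }
  out <- A
  for (L in unique(best_lag)) {
    cols <- which(best_lag == L)
    z <- max(1L, 1L + L):min(nz, nz + L)
    out[z, cols] <- (A[z, cols, drop = FALSE] + B[z - L, cols, drop = FALSE]) / 2
  }
  merged <- vol_a
  merged$intensity <- array(out, dim = d)
  attr(merged, "merge_lags") <- matrix(best_lag, d[2L], d[3L])
  merged
}
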