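# Enface reconstruction: the volume is resampled so the (rounded) reference
# surface lands on one constant plane, then planes are extracted at every
# integer depth offset (1 offset pixel = 4.13 um). Sampling is
# nearest-neighbour: every valid enface pixel equals exactly one input voxel,
# keeping the levels-times-4.13 arithmetic exact.

#' Flatten a volume to a reference surface
#'
#' `output[z', y, x] = input[round(surface[y, x]) + z' - z_ref, y, x]` with
#' `z_ref` the rounded median surface depth, so the reference surface maps
#' to the single plane `z' = z_ref`. Samples falling outside the input are
#' flagged in a validity channel (deep planes legitimately exit the volume
#' where the choroid is thin).
#'
#' @param volume an [oct_volume()].
#' @param surface a [surface_map()] valid everywhere, matching the lateral
#'   grid of `volume`.
#' @return An object of class `flat_volume`: fields `intensity` (3D array),
#'   `valid` (logical array), `reference_level` (0-based z index of the
#'   surface plane), `axial_pitch_um`, `lateral_pitch_um`, plus the source
#'   metadata.
#' @export
flatten_volume <- function(volume, surface) {
  stopifnot(inherits(volume, "oct_volume"), inherits(surface, "surface_map"))
  d <- dim(volume$intensity)
  if (!identical(dim(surface$depth), d[2:3])) {
    stop_enface("shape_mismatch", "surface and volume lateral grids differ.")
  }
  if (!all(surface$valid)) {
    stop_enface("bad_surface", "flattening requires a surface valid everywhere.")
  }
  nz <- d[1L]; npix <- d[2L] * d[3L]
  S <- as.integer(round(surface$depth))  # 0-based
  if (any(S < 0 | S > nz - 1)) {
    stop_enface("bad_surface", "surface depths outside the volume.")
  }
  z_ref <- as.integer(round(median(S)))
  # input z (0-based) feeding each output voxel
  zin <- outer(seq_len(nz) - 1L - z_ref, c(S), "+")
  ok <- zin >= 0L & zin <= nz - 1L
  lin <- (zin + 1L) + (rep(seq_len(npix), each = nz) - 1L) * nz
  M <- matrix(volume$intensity, nz, npix)
  out <- matrix(0, nz, npix)
  out[ok] <- M[lin[ok]]
  structure(list(
    intensity = array(out, d),
    valid = array(ok, d),
    reference_level = z_ref,
    axial_pitch_um = volume$axial_pitch_um,
    lateral_pitch_um = volume$lateral_pitch_um,
    subject_id = volume$subject_id,
    eye = volume$eye,
    age_years = volume$age_years
  ), class = "flat_volume")
}

#' Extract an enface stack from a flattened volume
#'
#' One plane per integer depth offset from the reference surface; offset 0
#' is the on-surface (RPE) plane and positive offsets point toward the
#' sclera. Per-plane masks are false where the flattening sampled outside
#' the input volume.
#'
#' @param flattened a `flat_volume` from [flatten_volume()].
#' @param offset_range length-2 integer `c(first, last)` offset, inclusive.
#' @return An object of class `enface_stack`: `planes` (array
#'   `[y, x, k]`), `valid` (logical array), `offsets`, `axial_pitch_um`,
#'   `lateral_pitch_um`.
#' @export
extract_enface_stack <- function(flattened, offset_range) {
  stopifnot(inherits(flattened, "flat_volume"))
  o <- as.integer(offset_range)
  if (length(o) != 2L || o[2] < o[1]) {
    stop_enface("bad_params", "offset_range must be c(first, last) with first <= last.")
  }
  nz <- dim(flattened$intensity)[1L]
  z <- flattened$reference_level + (o[1]:o[2]) + 1L  # 1-based slice index
  if (any(z < 1L | z > nz)) {
    stop_enface("bad_params", "offset_range exceeds the flattened volume depth.")
  }
  offs <- o[1]:o[2]
  planes <- aperm(flattened$intensity[z, , , drop = FALSE], c(2, 3, 1))
  valid <- aperm(flattened$valid[z, , , drop = FALSE], c(2, 3, 1))
  structure(list(
    planes = planes,
    valid = valid,
    offsets = offs,
    axial_pitch_um = flattened$axial_pitch_um,
    lateral_pitch_um = flattened$lateral_pitch_um
  ), class = "enface_stack")
}

#' @export
print.enface_stack <- function(x, ...) {
  cat(sprintf("<enface_stack> %d planes, offsets %d..%d (%.2f um/offset), %d x %d\n",
              length(x$offsets), min(x$offsets), max(x$offsets),
              x$axial_pitch_um, dim(x$planes)[1], dim(x$planes)[2]))
  invisible(x)
}
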