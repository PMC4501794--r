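# Core volumetric containers. An OCT volume is a 3D non-negative intensity
# grid indexed (z, y, x) with z = 0-based axial depth increasing from the
# vitreous toward the sclera, plus voxel spacing and subject metadata.

#' Construct an OCT intensity volume
#'
#' The raw imaging object of the pipeline: a swept-source OCT scan stored as
#' a 3D array indexed `[z, y, x]` with the first slice vitreous-most. Default
#' spacing corresponds to a 12 x 12 mm, 400 x 400 A-scan macular raster with
#' a 4.13 um axial pixel pitch.
#'
#' @param intensity numeric 3D array `[z, y, x]` of non-negative, finite
#'   backscatter intensities; every dimension must be at least 8.
#' @param axial_pitch_um axial voxel size in micrometres (default 4.13).
#' @param lateral_pitch_um lateral A-scan spacing in micrometres
#'   (default 30 = 12000/400).
#' @param subject_id subject identifier string.
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @param age_years subject age in years (may be `NA`).
#' @return An object of class `oct_volume`.
#' @examples
#' v <- oct_volume(array(runif(8 * 8 * 16), c(16, 8, 8)))
#' dim(v$intensity)
#' @export
oct_volume <- function(intensity,
                       axial_pitch_um = 4.13,
                       lateral_pitch_um = 30,
                       subject_id = "S000",
                       eye = c("OD", "OS"),
                       age_years = NA_real_) {
  eye <- match.arg(eye)
  if (!is.array(intensity) || length(dim(intensity)) != 3L) {
    stop_enface("bad_pixels", "`intensity` must be a 3D numeric array [z, y, x].")
  }
  if (!is.numeric(intensity)) {
    stop_enface("bad_pixels", "`intensity` must be numeric.")
  }
  if (any(dim(intensity) < 8L)) {
    stop_enface("bad_dims", "every volume dimension must be at least 8.")
  }
  if (anyNA(intensity) || any(!is.finite(intensity)) || any(intensity < 0)) {
    stop_enface("bad_pixels", "intensities must be finite and non-negative.")
  }
  if (!isTRUE(axial_pitch_um > 0) || !isTRUE(lateral_pitch_um > 0)) {
    stop_enface("bad_spacing", "voxel pitches must be positive.")
  }
  structure(
    list(
      intensity = intensity,
      axial_pitch_um = as.numeric(axial_pitch_um),
      lateral_pitch_um = as.numeric(lateral_pitch_um),
      subject_id = as.character(subject_id),
      eye = eye,
      age_years = as.numeric(age_years)
    ),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<oct_volume> %d x %d x %d (z,y,x), %.2f um axial / %.1f um lateral, subject %s %s\n",
    d[1], d[2], d[3], x$axial_pitch_um, x$lateral_pitch_um, x$subject_id, x$eye
  ))
  invisible(x)
}

#' Construct a reference surface map
#'
#' A 2D map of (real-valued, 0-based) axial indices over the en-face grid
#' `(y, x)`, typically the RPE/Bruch's membrane complex used as the enface
#' reference. Invalid positions (e.g. vessel shadows) are flagged in `valid`.
#'
#' @param depth numeric matrix of axial indices (pixels, 0-based).
#' @param valid logical matrix of the same shape; defaults to finite `depth`.
#' @param nz optional axial extent used to bound-check valid depths.
#' @return An object of class `surface_map`.
#' @export
surface_map <- function(depth, valid = NULL, nz = NULL) {
  if (!is.matrix(depth)) stop_enface("bad_surface", "`depth` must be a matrix.")
  if (is.null(valid)) valid <- is.finite(depth)
  if (!is.logical(valid) || !identical(dim(valid), dim(depth))) {
    stop_enface("bad_surface", "`valid` must be a logical matrix matching `depth`.")
  }
  if (any(valid & !is.finite(depth))) {
    stop_enface("bad_surface", "depth must be finite wherever valid.")
  }
  if (any(valid & depth < 0)) {
    stop_enface("bad_surface", "valid depths must be >= 0.")
  }
  if (!is.null(nz) && any(valid & depth > nz - 1)) {
    stop_enface("bad_surface", "valid depths must be <= nz - 1.")
  }
  structure(list(depth = depth, valid = valid), class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf(
    "<surface_map> %d x %d, %.1f%% valid, depth range [%.1f, %.1f]\n",
    nrow(x$depth), ncol(x$depth), 100 * mean(x$valid),
    suppressWarnings(min(x$depth[x$valid])),
    suppressWarnings(max(x$depth[x$valid]))
  ))
  invisible(x)
}
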