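# Thickness quantification: boundary levels convert to micrometres by
# levels x 4.13; absolute thicknesses add exactly (TC = CC + CV) and
# relative thicknesses are percentages of TC summing to 100 exactly.
# Fellow-eye values average arithmetically, percentages as percentages.

#' Convert a level count to micrometres
#'
#' @param n_levels non-negative integer number of enface depth levels.
#' @param axial_pitch_um axial pixel pitch (default 4.13).
#' @return `n_levels * axial_pitch_um`.
#' @examples
#' levels_to_microns(20)  # 82.6
#' levels_to_microns(92)  # 379.96
#' @export
levels_to_microns <- function(n_levels, axial_pitch_um = 4.13) {
  if (any(n_levels < 0)) stop_enface("bad_params", "level counts must be >= 0.")
  n_levels * axial_pitch_um
}

#' Thickness record of one eye from its boundary set
#'
#' CC spans RPE (offset 0) to the transition, CV the transition to the CSI;
#' TC = CC + CV and the relative thicknesses are their percentages of TC.
#'
#' @param boundaries a `layer_boundary_set` from [detect_boundaries()] (or a
#'   list with `rpe_level`, `transition_level`, `csi_level`).
#' @param axial_pitch_um axial pixel pitch.
#' @param subject_id,eye,group,age_years optional metadata carried into the
#'   record.
#' @return A one-row tibble: `subject_id`, `eye`, `group`, `age_years`,
#'   `tc_um`, `cc_um`, `cv_um`, `cc_pct`, `cv_pct`, `source = "enface"`.
#' @export
quantify_eye <- function(boundaries, axial_pitch_um = 4.13,
                         subject_id = NA_character_, eye = NA_character_,
                         group = NA_character_, age_years = NA_real_) {
  b <- boundaries
  if (!(b$rpe_level < b$transition_level && b$transition_level < b$csi_level)) {
    stop_enface("bad_boundaries", "boundaries must satisfy rpe < transition < csi.")
  }
  cc <- levels_to_microns(b$transition_level - b$rpe_level, axial_pitch_um)
  cv <- levels_to_microns(b$csi_level - b$transition_level, axial_pitch_um)
  tc <- cc + cv
  if (tc <= 0) stop_enface("bad_boundaries", "total choroidal thickness is zero.")
  cc_pct <- 100 * cc / tc
  tibble(
    subject_id = subject_id, eye = eye, group = group, age_years = age_years,
    tc_um = tc, cc_um = cc, cv_um = cv,
    cc_pct = cc_pct, cv_pct = 100 - cc_pct,
    source = "enface"
  )
}

#' Average the two eyes of a subject
#'
#' Arithmetic mean of each metric; relative thicknesses are averaged as
#' percentages, not recomputed from the averaged micrometre values.
#'
#' @param od,os one-row thickness records ([quantify_eye()]) of the same
#'   subject's right and left eye.
#' @return A one-row tibble: `subject_id`, `group`, `age_years`, and the
#'   eye-averaged `tc_um`, `cc_um`, `cv_um`, `cc_pct`, `cv_pct`.
#' @export
average_eyes <- function(od, os) {
  if (identical(od$eye, os$eye)) {
    stop_enface("bad_params", "average_eyes() needs two different eyes.")
  }
  if (!identical(od$subject_id, os$subject_id)) {
    stop_enface("bad_params", "records belong to different subjects.")
  }
  tibble(
    subject_id = od$subject_id,
    group = od$group,
    age_years = od$age_years,
    tc_um = (od$tc_um + os$tc_um) / 2,
    cc_um = (od$cc_um + os$cc_um) / 2,
    cv_um = (od$cv_um + os$cv_um) / 2,
    cc_pct = (od$cc_pct + os$cc_pct) / 2,
    cv_pct = (od$cv_pct + os$cv_pct) / 2
  )
}

#' Subfoveal TC from the horizontal B-scan (external reference method)
#'
#' Measures the total choroidal thickness on the horizontal cross-section
#' through the fovea, independently of the enface boundaries: each A-scan in
#' the foveal ROI row is scanned downward from the reference surface for the
#' deepest dark (vessel-lumen) run, the CSI is placed where the last
#' sustained dark run ends and the homogeneous region begins, and TC is the
#' foveal median of (CSI depth - surface depth) x 4.13. The classifier
#' smooths the B-scan in 2D and thresholds against the local mean with a
#' relative contrast floor; it reuses no enface outputs.
#'
#' @param volume an [oct_volume()].
#' @param surface the reference [surface_map()] (valid everywhere).
#' @param fovea `c(y, x)` fovea position (1-based pixels).
#' @param bp a [boundary_params()] (supplies `tau`-persistence and the
#'   B-scan contrast floor).
#' @return A one-row tibble with `source = "bscan"` and `tc_um`; `cc_um`,
#'   `cv_um` and the percentages are `NA` (the B-scan standard method
#'   measures TC only).
#' @export
measure_tc_bscan <- function(volume, surface, fovea, bp = boundary_params()) {
  stopifnot(inherits(volume, "oct_volume"), inherits(surface, "surface_map"))
  d <- dim(volume$intensity)
  if (fovea[1] < 1 || fovea[1] > d[2] || fovea[2] < 1 || fovea[2] > d[3]) {
    stop_enface("bad_params", "fovea position outside the grid.")
  }
  y <- as.integer(round(fovea[1]))
  half_roi <- 500 / volume$lateral_pitch_um
  xs <- which(abs(seq_len(d[3]) - fovea[2]) <= half_roi)
  bscan <- volume$intensity[, y, , drop = TRUE]          # z by x
  # drop retinal-vessel shadow columns (near-total attenuation)
  energy <- colSums(bscan^2)
  xs <- xs[energy[xs] >= 0.3 * median(energy)]
  if (!length(xs)) stop_enface("csi_not_found", "all foveal A-scans are shadowed.")
  ps <- gauss_smooth2d(bscan, 1.5)
  # dark relative to the typical sub-surface (choroid + sclera) intensity; a
  # sliding local mean would fail where large lumens fill the window
  sub <- unlist(lapply(xs, function(x) {
    s0 <- as.integer(round(surface$depth[y, x]))
    ps[min(s0 + 3L, d[1L]):d[1L], x]
  }))
  dark_all <- ps < (1 - bp$bscan_contrast_floor) * median(sub)
  offs <- rep(NA_real_, length(xs))
  for (i in seq_along(xs)) {
    x <- xs[i]
    s0 <- as.integer(round(surface$depth[y, x]))
    z <- (s0 + 3L):d[1L]                                  # 1-based: below the RPE band
    if (length(z) < bp$persistence_csi + 2L) next
    dk <- dark_all[z, x]
    run <- rle(dk)
    ends <- cumsum(run$lengths)
    deep <- which(run$values & run$lengths >= 2L)         # sustained dark runs
    if (!length(deep)) { offs[i] <- 0; next }
    last_end <- ends[max(deep)]
    if (length(dk) - last_end < bp$persistence_csi) next  # CSI beyond the volume
    offs[i] <- (z[last_end] - 1L) + 1L - surface$depth[y, x]  # first homogeneous z
  }
  if (all(is.na(offs))) {
    stop_enface("csi_not_found", "B-scan CSI not found within the volume.")
  }
  tc <- median(offs, na.rm = TRUE) * volume$axial_pitch_um
  tibble(
    subject_id = volume$subject_id, eye = volume$eye, group = NA_character_,
    age_years = volume$age_years,
    tc_um = tc, cc_um = NA_real_, cv_um = NA_real_,
    cc_pct = NA_real_, cv_pct = NA_real_,
    source = "bscan"
  )
}
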