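# Choroidal layer boundaries from plane texture. The choriocapillaris
# appears as fine reticular structure (dark components below a lateral
# scale cutoff), the choroidal vessels as coarse interwoven lumens; the
# CC-to-CV transition is the depth at which the coarse fraction overtakes
# the fine fraction ("features of both layers in equal proportions"), and
# the choroidal-scleral interface is the depth at which dark lumen
# structure vanishes from the foveal area.

#' Circular region-of-interest mask
#'
#' @param dim length-2 grid dimensions `c(ny, nx)`.
#' @param center `c(y, x)` center in pixels (1-based).
#' @param radius_mm circle radius in millimetres (3.0 for the 6-mm macular
#'   area, 0.5 for the 1-mm foveal area).
#' @param lateral_pitch_um lateral pixel pitch in micrometres.
#' @return Logical matrix, clipped to the grid.
#' @export
roi_mask <- function(dim, center, radius_mm, lateral_pitch_um = 30) {
  r_px <- radius_mm * 1000 / lateral_pitch_um
  dy <- matrix(seq_len(dim[1]) - center[1], dim[1], dim[2])
  dx <- matrix(seq_len(dim[2]) - center[2], dim[1], dim[2], byrow = TRUE)
  dy^2 + dx^2 <= r_px^2
}

#' Boundary-detection parameters
#'
#' @param window_px sliding-window side (pixels) of the local mean/SD used
#'   by the lumen classifier.
#' @param alpha lumen threshold: a pixel is dark when below
#'   `local mean - alpha * local SD`.
#' @param contrast_floor additional relative floor: a dark pixel must also
#'   lie below `(1 - contrast_floor) * local mean`. Keeps homogeneous
#'   speckled regions (sclera) from producing spurious dark fractions.
#' @param smooth_sigma_px lateral Gaussian pre-smoothing of each plane
#'   before classification (speckle suppression); 0 disables.
#' @param scale_cutoff_px equivalent-diameter cutoff (pixels) separating
#'   fine (capillary-scale) from coarse (vessel-scale) dark components;
#'   4 px is about 120 um laterally.
#' @param tau_csi maximum foveal dark fraction of a sclera plane.
#' @param persistence_transition,persistence_csi number of consecutive
#'   offsets a crossing / sclera condition must persist (speckle debounce).
#' @param profile_smooth_window moving-average window over offsets applied
#'   to the fine/coarse fractions before the crossing search.
#' @param bscan_contrast_floor relative contrast floor of the independent
#'   B-scan CSI detector.
#' @return A list of class `boundary_params`.
#' @export
boundary_params <- function(window_px = 15L, alpha = 0.3,
                            contrast_floor = 0.2, smooth_sigma_px = 1.2,
                            scale_cutoff_px = 4, tau_csi = 0.05,
                            persistence_transition = 2L, persistence_csi = 3L,
                            profile_smooth_window = 3L,
                            bscan_contrast_floor = 0.3) {
  structure(as.list(environment()), class = "boundary_params")
}

.classify_dark <- function(plane, valid, bp) {
  p <- plane
  p[!valid] <- NA_real_
  ps <- gauss_smooth2d(p, bp$smooth_sigma_px)
  st <- box_stats(ps, bp$window_px)
  dark <- ps < (st$mean - bp$alpha * st$sd) &
    ps < (1 - bp$contrast_floor) * st$mean
  dark[!valid | !is.finite(ps)] <- FALSE
  dark
}

#' Texture features of one enface plane
#'
#' Classifies vessel-lumen pixels with a local adaptive threshold on the
#' (speckle-smoothed) plane, labels connected dark components, and splits
#' the dark area into fine and coarse fractions by equivalent diameter
#' against `scale_cutoff_px`.
#'
#' @param plane numeric matrix.
#' @param valid logical matrix of usable pixels (sampling validity).
#' @param roi logical ROI mask (see [roi_mask()]).
#' @param bp a [boundary_params()].
#' @return A one-row tibble: `dark_fraction`, `fine_fraction`,
#'   `coarse_fraction`, `valid_fraction`, `low_confidence`.
#' @export
compute_plane_features <- function(plane, valid, roi, bp = boundary_params()) {
  if (!any(roi)) stop_enface("empty_roi", "ROI contains no pixels.")
  v <- roi & valid
  valid_fraction <- sum(v) / sum(roi)
  if (!any(v)) {
    return(tibble(dark_fraction = 0, fine_fraction = 0, coarse_fraction = 0,
                  valid_fraction = 0, low_confidence = TRUE))
  }
  dark <- .classify_dark(plane, valid, bp)
  dark_roi <- dark & v
  dark_fraction <- sum(dark_roi) / sum(v)
  fine_fraction <- 0
  coarse_fraction <- 0
  if (any(dark_roi)) {
    # components labelled on the full dark mask so vessels crossing the ROI
    # rim keep their true scale; areas counted inside the ROI
    lab <- EBImage::bwlabel(dark)
    areas <- tabulate(lab[lab > 0])
    eqd <- sqrt(4 * areas / pi)
    lab_roi <- lab[dark_roi]
    fine_area <- sum(eqd[lab_roi] < bp$scale_cutoff_px)
    fine_fraction <- fine_area / length(lab_roi)
    coarse_fraction <- 1 - fine_fraction
  }
  tibble(dark_fraction = dark_fraction, fine_fraction = fine_fraction,
         coarse_fraction = coarse_fraction, valid_fraction = valid_fraction,
         low_confidence = valid_fraction < 0.5)
}

#' Per-offset texture profiles of an enface stack
#'
#' Computes [compute_plane_features()] for every plane on the macular ROI
#' and, in parallel, the foveal-ROI dark fraction used by CSI detection.
#'
#' @param stack an [extract_enface_stack()] result.
#' @param fovea_center `c(y, x)` fovea position (1-based pixels).
#' @param bp a [boundary_params()].
#' @param exclude optional lateral logical matrix of A-scan positions to
#'   exclude at every depth (e.g. retinal-vessel shadow columns, which
#'   project as dark vessel-shaped artefacts onto every plane).
#' @return A tibble with one row per offset: macular features plus
#'   `dark_fraction_fov` and `valid_fraction_fov`.
#' @export
plane_profiles <- function(stack, fovea_center, bp = boundary_params(),
                           exclude = NULL) {
  stopifnot(inherits(stack, "enface_stack"))
  d <- dim(stack$planes)[1:2]
  mac <- roi_mask(d, fovea_center, 3.0, stack$lateral_pitch_um)
  fov <- roi_mask(d, fovea_center, 0.5, stack$lateral_pitch_um)
  purrr::map_dfr(seq_along(stack$offsets), function(k) {
    plane <- stack$planes[, , k]
    valid <- stack$valid[, , k]
    if (!is.null(exclude)) valid <- valid & !exclude
    f <- compute_plane_features(plane, valid, mac, bp)
    vf <- fov & valid
    dark <- .classify_dark(plane, valid, bp)
    f$dark_fraction_fov <- if (any(vf)) sum(dark & vf) / sum(vf) else 0
    f$valid_fraction_fov <- sum(vf) / sum(fov)
    f$offset <- stack$offsets[k]
    f
  }) |> dplyr::relocate("offset")
}

#' Detect the CC-to-CV transition level
#'
#' Smooths the fine and coarse fractions across depth and returns the
#' smallest offset at which the coarse fraction reaches the fine fraction
#' (with dark structure present) and stays there for
#' `persistence_transition` consecutive offsets — the computable reading of
#' "features of both layers distributed in equal proportions". Without a
#' crossing, the midpoint of the dark-fraction plateau is returned flagged
#' low-confidence.
#'
#' @param profiles a [plane_profiles()] tibble (at least 4 rows, macular
#'   ROI features).
#' @param bp a [boundary_params()].
#' @return list with `level` (integer offset) and `low_confidence`.
#' @export
detect_transition <- function(profiles, bp = boundary_params()) {
  if (nrow(profiles) < 4L) {
    stop_enface("bad_params", "need at least 4 plane profiles.")
  }
  profiles <- dplyr::arrange(profiles, .data$offset)
  fine <- moving_average(profiles$fine_fraction, bp$profile_smooth_window)
  coarse <- moving_average(profiles$coarse_fraction, bp$profile_smooth_window)
  cross <- coarse >= fine & profiles$dark_fraction > 0
  run <- rle(cross)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  hit <- which(run$values & run$lengths >= bp$persistence_transition)
  if (length(hit)) {
    return(list(level = as.integer(profiles$offset[starts[hit[1]]]),
                low_confidence = FALSE))
  }
  # fallback: midpoint of the dark-structure plateau
  dk <- profiles$dark_fraction
  plateau <- which(dk >= 0.5 * max(dk))
  list(level = as.integer(round(median(profiles$offset[plateau]))),
       low_confidence = TRUE)
}

#' Detect the choroidal-scleral interface level
#'
#' Returns the smallest offset beyond the transition at which the foveal
#' dark fraction stays below `tau_csi` for `persistence_csi` consecutive
#' offsets — the depth where choroidal vessels vanish from the foveal area
#' and the homogeneous sclera begins. Falls back to the macular dark
#' fraction when the foveal ROI is mostly invalid.
#'
#' @param profiles a [plane_profiles()] tibble.
#' @param transition_level offset returned by [detect_transition()].
#' @param bp a [boundary_params()].
#' @return list with `level` (integer offset) and `low_confidence`.
#' @export
detect_csi <- function(profiles, transition_level, bp = boundary_params()) {
  if (nrow(profiles) < 4L) {
    stop_enface("bad_params", "need at least 4 plane profiles.")
  }
  profiles <- dplyr::arrange(profiles, .data$offset)
  use_fov <- all(c("dark_fraction_fov", "valid_fraction_fov") %in% names(profiles)) &&
    mean(profiles$valid_fraction_fov) >= 0.5
  dk <- if (use_fov) profiles$dark_fraction_fov else profiles$dark_fraction
  idx <- which(profiles$offset > transition_level)
  quiet <- dk[idx] < bp$tau_csi
  run <- rle(quiet)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  hit <- which(run$values & run$lengths >= bp$persistence_csi)
  if (!length(hit)) {
    stop_enface("csi_not_found",
                "no sustained vessel-free plane: the choroid exceeds the stack depth.")
  }
  list(level = as.integer(profiles$offset[idx[starts[hit[1]]]]),
       low_confidence = !use_fov)
}

#' Detect the full boundary set of one eye
#'
#' Convenience wrapper running [plane_profiles()], [detect_transition()] and
#' [detect_csi()] on an enface stack.
#'
#' @inheritParams plane_profiles
#' @return A list of class `layer_boundary_set`: `rpe_level` (0),
#'   `transition_level`, `csi_level`, confidence flags, and the profile
#'   tibble.
#' @export
detect_boundaries <- function(stack, fovea_center, bp = boundary_params()) {
  profiles <- plane_profiles(stack, fovea_center, bp)
  tr <- detect_transition(profiles, bp)
  cs <- detect_csi(profiles, tr$level, bp)
  if (!(0 < tr$level && tr$level < cs$level)) {
    stop_enface("bad_boundaries",
                sprintf("boundary ordering violated: transition %d, CSI %d.",
                        tr$level, cs$level))
  }
  structure(list(
    rpe_level = 0L,
    transition_level = tr$level,
    csi_level = cs$level,
    transition_low_confidence = tr$low_confidence,
    csi_low_confidence = cs$low_confidence,
    profiles = profiles
  ), class = "layer_boundary_set")
}
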