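# Synthetic scene renderer. Builds, from the vitreous down: a retina band
# with retinal-vessel shadow lines; a bright RPE/Bruch's band on a smooth
# curved surface; a choriocapillaris (CC) band of fine sub-resolution
# reticular texture; a choroidal-vessel (CV) band of dark tubular lumens
# whose radii grow with depth; and homogeneous sclera beyond the
# choroidal-scleral interface (CSI). The noise-free scene is then blurred
# axially by the system PSF and multiplied by gamma speckle of mean 1.
# Ground-truth surfaces are recorded before blur and noise.

#' Rendering parameters for synthetic OCT volumes
#'
#' Band reflectivities are relative backscatter levels; the RPE band is
#' strictly the brightest, choroidal vessel lumens the darkest. The default
#' grid (224 x 64 x 64) is a desk-scale central crop of the 12 x 12 mm
#' protocol at native 4.13 um axial / 30 um lateral pitch; a full
#' 512 x 400 x 400 grid is supported by the same code path.
#'
#' @param nz,ny,nx grid dimensions (axial, slow, fast).
#' @param intensity_retina,intensity_rpe,intensity_cc_matrix,intensity_cc_dots,intensity_cv_wall,intensity_cv_lumen,intensity_sclera
#'   band reflectivities; all non-negative, `intensity_rpe` strictly largest.
#' @param rpe_depth_px axial index of the RPE surface at the fovea.
#' @param rpe_curvature_px posterior-pole curvature amplitude (pixels):
#'   added RPE depth at the grid corner relative to the fovea.
#' @param cc_texture_scale_px inner Gaussian scale of the band-pass
#'   (difference-of-Gaussians) field thresholded into the CC reticular
#'   texture; 1-2 px emulates capillary structure below the 30 um lateral
#'   resolution.
#' @param cc_dot_fraction areal fraction of dark texture in the CC band.
#' @param vessel_radius_px length-2 lumen radius (pixels) at the inner and
#'   outer edge of the CV band; radii grow linearly with depth.
#' @param vessel_length_px length-2 range of vessel segment lengths (pixels).
#' @param lumen_target_fraction length-2 per-level dark-lumen areal fraction
#'   the vessel sampler fills toward at the inner and outer edge of the CV
#'   band, assessed over the central (foveal) disc; the deep choroid
#'   (Haller's layer) is vessel-dominated, so the fraction grows with depth.
#' @param max_segment_tries per-level cap on segment draws.
#' @param n_shadows number of retinal-vessel shadow lines.
#' @param shadow_attenuation multiplicative attenuation of shadowed A-scans.
#' @param speckle_k gamma shape of the multiplicative speckle (mean 1,
#'   variance 1/k); `Inf` disables noise.
#' @param psf_sigma_px axial PSF sigma in pixels (default 1.5, i.e. ~6 um
#'   axial resolution at 4.13 um pitch); 0 disables blur.
#' @param thickness_variation_px smooth peripheral choroidal thinning
#'   amplitude (pixels) imposed on the CSI; the sampled thickness holds
#'   exactly at the foveal center.
#' @return A list of class `render_params`.
#' @export
render_params <- function(nz = 192L, ny = 64L, nx = 64L,
                          intensity_retina = 0.4,
                          intensity_rpe = 1.0,
                          intensity_cc_matrix = 0.62,
                          intensity_cc_dots = 0.18,
                          intensity_cv_wall = 0.55,
                          intensity_cv_lumen = 0.12,
                          intensity_sclera = 0.5,
                          rpe_depth_px = 28,
                          rpe_curvature_px = 4,
                          cc_texture_scale_px = 0.8,
                          cc_dot_fraction = 0.25,
                          vessel_radius_px = c(1.8, 5),
                          vessel_length_px = c(15, 40),
                          lumen_target_fraction = c(0.25, 0.55),
                          max_segment_tries = 80L,
                          n_shadows = 4L,
                          shadow_attenuation = 0.15,
                          speckle_k = 4,
                          psf_sigma_px = 1.5,
                          thickness_variation_px = 1) {
  rp <- as.list(environment())
  ints <- unlist(rp[grep("^intensity_", names(rp))])
  if (any(ints < 0)) stop_enface("bad_params", "band intensities must be >= 0.")
  if (any(ints[names(ints) != "intensity_rpe"] >= rp$intensity_rpe)) {
    stop_enface("bad_params", "the RPE band intensity must be strictly greatest.")
  }
  if (!isTRUE(rp$speckle_k > 0)) stop_enface("bad_params", "speckle_k must be > 0.")
  structure(rp, class = "render_params")
}

# Thresholded difference-of-Gaussians field: TRUE on the darkest
# `fraction` of a band-pass random field, giving 1-2 px reticular blobs.
.cc_texture_slice <- function(ny, nx, scale_px, fraction) {
  n <- matrix(rnorm(ny * nx), ny, nx)
  bp <- gauss_smooth2d(n, scale_px) - gauss_smooth2d(n, 3 * scale_px)
  bp <= quantile(bp, fraction)
}

# Rasterise one vessel segment tube into the lumen mask array (levels, y, x).
.add_segment <- function(lum, oc, r, cy, cx, theta, len, o0) {
  ux <- cos(theta); uy <- sin(theta)
  p0 <- c(cy - uy * len / 2, cx - ux * len / 2)
  p1 <- c(cy + uy * len / 2, cx + ux * len / 2)
  n_lev <- dim(lum)[1L]; ny <- dim(lum)[2L]; nx <- dim(lum)[3L]
  for (l in seq_len(n_lev)) {
    o <- o0 + l - 1L
    dz <- o - oc
    if (abs(dz) > r) next
    w <- max(0.5, sqrt(r^2 - dz^2))
    y1 <- max(1L, floor(min(p0[1], p1[1]) - w)); y2 <- min(ny, ceiling(max(p0[1], p1[1]) + w))
    x1 <- max(1L, floor(min(p0[2], p1[2]) - w)); x2 <- min(nx, ceiling(max(p0[2], p1[2]) + w))
    if (y1 > y2 || x1 > x2) next
    gy <- y1:y2; gx <- x1:x2
    py <- matrix(gy, length(gy), length(gx))
    px <- matrix(gx, length(gy), length(gx), byrow = TRUE)
    vy <- p1[1] - p0[1]; vx <- p1[2] - p0[2]
    tt <- ((py - p0[1]) * vy + (px - p0[2]) * vx) / (vy^2 + vx^2)
    tt <- pmin(1, pmax(0, tt))
    d2 <- (py - (p0[1] + tt * vy))^2 + (px - (p0[2] + tt * vx))^2
    sub <- lum[l, gy, gx]
    sub[d2 <= w^2] <- TRUE
    lum[l, gy, gx] <- sub
  }
  lum
}

# Noise-free scene + ground truth for one eye. Consumes RNG.
.render_scene <- function(tc_um, cc_um, rp, axial_pitch_um = 4.13,
                          lateral_pitch_um = 30) {
  nz <- rp$nz; ny <- rp$ny; nx <- rp$nx
  tc_levels <- round(tc_um / axial_pitch_um)
  cc_levels <- round(cc_um / axial_pitch_um)
  if (cc_levels < 3L || tc_levels - cc_levels < 3L) {
    stop_enface("bad_params", "each choroidal layer must span at least 3 levels.")
  }
  fy <- ceiling(ny / 2); fx <- ceiling(nx / 2)
  dy <- matrix(seq_len(ny) - fy, ny, nx)
  dx <- matrix(seq_len(nx) - fx, ny, nx, byrow = TRUE)
  r2n <- (dy^2 + dx^2) / ((ny / 2)^2 + (nx / 2)^2)
  R <- rp$rpe_depth_px + rp$rpe_curvature_px * r2n
  tvar <- rp$thickness_variation_px * r2n
  csi <- R + tc_levels - tvar
  if (max(csi) + 4 + ceiling(3 * rp$psf_sigma_px) > nz - 1) {
    stop_enface("choroid_overflow",
                sprintf("choroid (CSI at %.1f px) does not fit in nz = %d.",
                        max(csi), nz))
  }
  if (min(R) < 8) stop_enface("choroid_overflow", "RPE too close to the top of the grid.")

  # real-valued offset from the RPE surface for every voxel
  offr <- array(seq_len(nz) - 1, c(nz, ny, nx)) -
    aperm(array(R, c(ny, nx, nz)), c(3, 1, 2))
  csi_off <- aperm(array(tc_levels - tvar, c(ny, nx, nz)), c(3, 1, 2))

  scene <- array(rp$intensity_retina, c(nz, ny, nx))
  in_rpe <- abs(offr) <= 1.5
  scene[in_rpe] <- rp$intensity_rpe * (1 - 0.1 * abs(offr[in_rpe]))
  in_cc <- offr > 1.5 & offr < cc_levels - 0.5
  in_cv <- offr >= cc_levels - 0.5 & offr < csi_off - 0.5
  in_sclera <- offr >= csi_off - 0.5

  # CC: per-level reticular dot texture, offsets 2 .. cc_levels - 1
  n_cc <- cc_levels - 2L
  cc_tex <- array(FALSE, c(n_cc, ny, nx))
  for (l in seq_len(n_cc)) {
    cc_tex[l, , ] <- .cc_texture_slice(ny, nx, rp$cc_texture_scale_px,
                                       rp$cc_dot_fraction)
  }
  vox <- which(in_cc)
  zi <- (vox - 1L) %% nz + 1L
  rest <- (vox - 1L) %/% nz
  yi <- rest %% ny + 1L
  xi <- rest %/% ny + 1L
  oi <- pmin(pmax(round(offr[vox]) - 1L, 1L), n_cc)
  dark <- cc_tex[cbind(oi, yi, xi)]
  scene[vox] <- ifelse(dark, rp$intensity_cc_dots, rp$intensity_cc_matrix)

  # CV: dark tubular lumens, offsets cc_levels .. tc_levels - 1, filled
  # level by level toward the target areal fraction over the central disc
  n_cv <- tc_levels - cc_levels
  lum <- array(FALSE, c(n_cv, ny, nx))
  check_r <- min(500 / lateral_pitch_um, min(ny, nx) / 2 - 1)
  disc <- (dy^2 + dx^2) <= check_r^2
  macula_r_px <- 3000 / lateral_pitch_um
  for (l in seq_len(n_cv)) {
    oc_level <- cc_levels + l - 1L
    frac <- (l - 1) / max(1L, n_cv - 1L)
    r <- rp$vessel_radius_px[1] + diff(rp$vessel_radius_px) * frac
    target <- rp$lumen_target_fraction[1] +
      diff(range(rp$lumen_target_fraction)) * frac
    tries <- 0L
    while (mean(lum[l, , ][disc]) < target &&
           tries < rp$max_segment_tries) {
      tries <- tries + 1L
      cy <- runif(1, 1, ny); cx <- runif(1, 1, nx)
      ecc <- sqrt((cy - fy)^2 + (cx - fx)^2)
      theta <- if (ecc > macula_r_px) {
        atan2(cy - fy, cx - fx) + rnorm(1, 0, 0.15)
      } else {
        runif(1, 0, pi)
      }
      len <- runif(1, rp$vessel_length_px[1], rp$vessel_length_px[2])
      lum <- .add_segment(lum, oc_level + runif(1, -0.5, 0.5), r,
                          cy, cx, theta, len, cc_levels)
    }
  }
  vox <- which(in_cv)
  zi <- (vox - 1L) %% nz + 1L
  rest <- (vox - 1L) %/% nz
  yi <- rest %% ny + 1L
  xi <- rest %/% ny + 1L
  oi <- pmin(pmax(round(offr[vox]) - cc_levels + 1L, 1L), n_cv)
  in_lum <- lum[cbind(oi, yi, xi)]
  scene[vox] <- ifelse(in_lum, rp$intensity_cv_lumen, rp$intensity_cv_wall)

  scene[in_sclera] <- rp$intensity_sclera

  # retinal-vessel shadows: thin straight chords, whole A-scan attenuated
  shadow <- matrix(FALSE, ny, nx)
  if (rp$n_shadows > 0) {
    for (s in seq_len(rp$n_shadows)) {
      th <- runif(1, 0, pi)
      p0 <- c(runif(1, 1, ny), runif(1, 1, nx))
      nrm <- c(-sin(th + pi / 2), cos(th + pi / 2))
      dist <- abs((matrix(seq_len(ny), ny, nx) - p0[1]) * nrm[1] +
                    (matrix(seq_len(nx), ny, nx, byrow = TRUE) - p0[2]) * nrm[2])
      shadow <- shadow | dist <= 0.6
    }
    m <- matrix(scene, nz)
    m[, c(shadow)] <- m[, c(shadow), drop = FALSE] * rp$shadow_attenuation
    scene <- array(m, c(nz, ny, nx))
  }

  truth <- structure(list(
    rpe_surface = surface_map(R, nz = nz),
    transition_surface = surface_map(R + cc_levels, nz = nz),
    csi_surface = surface_map(csi, nz = nz),
    true_tc_levels = as.integer(tc_levels),
    true_cc_levels = as.integer(cc_levels),
    fovea_center = c(y = fy, x = fx),
    shadow_mask = shadow
  ), class = "scene_truth")
  list(scene = scene, truth = truth)
}

# PSF blur + multiplicative speckle. Consumes RNG when speckle is finite.
.apply_noise <- function(scene, rp) {
  out <- gauss_smooth_axial(scene, rp$psf_sigma_px)
  if (is.finite(rp$speckle_k)) {
    out <- out * array(rgamma(length(out), shape = rp$speckle_k,
                              rate = rp$speckle_k), dim = dim(out))
  }
  out
}

.shift_axial <- function(a, s) {
  if (s == 0) return(a)
  nz <- dim(a)[1L]
  src <- pmin(pmax(seq_len(nz) - s, 1L), nz)
  a[src, , , drop = FALSE]
}

#' Render one synthetic eye
#'
#' @param eye_row a one-row data frame (as produced by [sample_cohort()])
#'   with `tc_um`, `cc_um` and optionally `subject_id`, `eye`, `age_years`.
#' @param rp a [render_params()].
#' @param seed integer seed; the volume is bit-reproducible given
#'   `(eye_row, rp, seed)`.
#' @return list with `volume` (an [oct_volume()]) and `truth` (a
#'   `scene_truth`: ground-truth RPE/transition/CSI surfaces, level counts
#'   at the foveal center, fovea position and shadow mask).
#' @export
render_volume <- function(eye_row, rp = render_params(), seed = 1L) {
  withr::with_seed(seed, {
    sc <- .render_scene(eye_row$tc_um, eye_row$cc_um, rp)
    vol <- oct_volume(.apply_noise(sc$scene, rp),
                      subject_id = eye_row$subject_id %||% "S000",
                      eye = eye_row$eye %||% "OD",
                      age_years = eye_row$age_years %||% NA_real_)
    list(volume = vol, truth = sc$truth)
  })
}

#' Render both eyes of a subject, two speckle realizations each
#'
#' Emulates the acquisition protocol of at least two volumetric scans per
#' eye: the same noise-free scene is rendered twice with independent
#' speckle, the second realization optionally shifted axially by a small
#' random integer to exercise the merge step.
#'
#' @param subject_rows two rows of a [sample_cohort()] tibble (OD and OS of
#'   one subject).
#' @param rp a [render_params()].
#' @param seed integer master seed for the subject.
#' @param shift_max maximum |axial shift| (pixels) applied to the second
#'   realization; 0 disables shifting.
#' @param realization_seeds optional length-2 integer seeds for the two
#'   speckle draws (shared across eyes); defaults derive from `seed`.
#' @return A list with one element per eye: `truth`, `realizations` (list of
#'   two [oct_volume()]), and `shift` (pixels applied to realization 2).
#' @export
render_subject <- function(subject_rows, rp = render_params(), seed = 1L,
                           shift_max = 0L, realization_seeds = NULL) {
  stopifnot(nrow(subject_rows) == 2L)
  if (length(unique(subject_rows$eye)) != 2L) {
    stop_enface("bad_params", "subject_rows must contain one OD and one OS row.")
  }
  out <- list()
  for (e in 1:2) {
    row <- subject_rows[e, ]
    sc <- withr::with_seed(child_seed(seed, e), .render_scene(row$tc_um, row$cc_um, rp))
    s <- if (shift_max > 0) {
      withr::with_seed(child_seed(seed, 100L + e),
                       sample(seq(-shift_max, shift_max), 1L))
    } else 0L
    seeds <- realization_seeds %||% c(child_seed(seed, 10L + 2L * e),
                                      child_seed(seed, 11L + 2L * e))
    mk <- function(scene, noise_seed) {
      withr::with_seed(noise_seed,
                       oct_volume(.apply_noise(scene, rp),
                                  subject_id = row$subject_id %||% "S000",
                                  eye = row$eye, age_years = row$age_years %||% NA_real_))
    }
    out[[row$eye]] <- list(
      truth = sc$truth,
      realizations = list(mk(sc$scene, seeds[1]),
                          mk(.shift_axial(sc$scene, s), seeds[2])),
      shift = s
    )
  }
  out
}
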