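# Shared fixtures, built once per test session and memoised: rendering and
# analysing volumes is the expensive part of this suite, so tests share a
# small bank of rendered eyes and one full pipeline run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# noise-free, blur-free, flat-surface render parameters
noise_free_params <- function(...) {
  render_params(speckle_k = Inf, psf_sigma_px = 0, rpe_curvature_px = 0,
                n_shadows = 0, thickness_variation_px = 0, ...)
}

# one eye row with exact level counts (92 TC / 20 CC levels at 4.13 um)
eye_row_levels <- function(tc_levels = 92, cc_levels = 20) {
  tibble::tibble(subject_id = "S001", group = "young", age_years = 30,
                 eye = "OD", tc_um = tc_levels * 4.13, cc_um = cc_levels * 4.13)
}

# a rendered noise-free eye (flat RPE), shared by exactness tests
noise_free_eye <- function() {
  fixture("noise_free_eye", function() {
    render_volume(eye_row_levels(), noise_free_params(), seed = 101)
  })
}

# curved noise-free eye (surface curvature + peripheral thinning kept)
noise_free_eye2 <- function() {
  fixture("noise_free_eye2", function() {
    rp <- render_params(speckle_k = Inf, psf_sigma_px = 0, n_shadows = 0)
    render_volume(eye_row_levels(), rp, seed = 102)
  })
}

# default-noise rendered eyes (speckle k = 4), one per seed
speckled_eye <- function(seed) {
  fixture(paste0("speckled_eye_", seed), function() {
    co <- sample_cohort(cohort_spec(n_young = 1, n_old = 0, seed = 400 + seed))
    render_volume(co[1, ], render_params(), seed = seed)
  })
}

# a merged-and-analysed eye under default noise (the study protocol merges
# two acquisitions per eye)
analysed_eye <- function(seed) {
  fixture(paste0("analysed_eye_", seed), function() {
    co <- sample_cohort(cohort_spec(n_young = 1, n_old = 0, seed = 400 + seed))
    rend <- render_subject(co[1:2, ], render_params(), seed = seed, shift_max = 3)
    od <- rend$OD
    merged <- merge_volumes(od$realizations[[1]], od$realizations[[2]])
    surface <- segment_rpe(merged)
    flat <- flatten_volume(merged, surface)
    nz <- dim(flat$intensity)[1]
    stack <- extract_enface_stack(flat, c(1, nz - 1 - flat$reference_level))
    shadow <- matrix(colSums(matrix(merged$intensity, nz)^2) <
                       0.3 * median(colSums(matrix(merged$intensity, nz)^2)),
                     dim(merged$intensity)[2], dim(merged$intensity)[3])
    profiles <- plane_profiles(stack, od$truth$fovea_center, boundary_params(),
                               exclude = shadow)
    list(truth = od$truth, merged = merged, surface = surface, stack = stack,
         shadow = shadow, profiles = profiles)
  })
}

# the 20-eye default-noise cohort run shared by recovery/validation tests
cohort_run <- function() {
  fixture("cohort_run", function() {
    run_pipeline(pipeline_config(cohort = cohort_spec(n_young = 5, n_old = 5),
                                 seed = 11))
  })
}

# two repeated tiny pipeline runs written to disk (determinism checks)
tiny_run_files <- function() {
  fixture("tiny_run_files", function() {
    cfg <- pipeline_config(cohort = cohort_spec(n_young = 2, n_old = 2),
                           seed = 7, keep_stacks = FALSE)
    d1 <- file.path(tempdir(), "run_a")
    d2 <- file.path(tempdir(), "run_b")
    r1 <- run_pipeline(cfg, out_dir = d1)
    r2 <- run_pipeline(cfg, out_dir = d2)
    list(run1 = r1, run2 = r2,
         csv1 = file.path(d1, "thickness.csv"),
         csv2 = file.path(d2, "thickness.csv"))
  })
}

# synthetic step-profile tibbles for the boundary-rule contract tests
step_profiles <- function(n = 30, transition = 20, csi = NULL,
                          dark = 0.5) {
  p <- tibble::tibble(
    offset = seq_len(n),
    dark_fraction = dark,
    fine_fraction = as.numeric(seq_len(n) < transition),
    coarse_fraction = as.numeric(seq_len(n) >= transition),
    valid_fraction = 1,
    low_confidence = FALSE,
    dark_fraction_fov = dark,
    valid_fraction_fov = 1
  )
  if (!is.null(csi)) {
    p$dark_fraction[p$offset >= csi] <- 0
    p$dark_fraction_fov[p$offset >= csi] <- 0
  }
  p
}
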