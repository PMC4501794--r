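# Scene renderer: layer geometry, ground truth bookkeeping, noise model.

test_that("noise-free rendering reproduces band intensities exactly", {
  rv <- noise_free_eye()
  rp <- noise_free_params()
  # deep sclera voxels carry the sclera reflectivity exactly
  deep <- rv$volume$intensity[rp$nz - 2, , ]
  expect_true(all(deep == rp$intensity_sclera))
  # the on-surface plane carries the full RPE reflectivity
  z_rpe <- round(rv$truth$rpe_surface$depth[1, 1]) + 1
  expect_true(all(rv$volume$intensity[z_rpe, , ] == rp$intensity_rpe))
})

test_that("ground-truth level counts equal round(um / 4.13) by construction", {
  rv <- noise_free_eye()  # rendered from 92 and 20 levels exactly
  expect_identical(rv$truth$true_tc_levels, 92L)
  expect_identical(rv$truth$true_cc_levels, 20L)
  fc <- rv$truth$fovea_center
  expect_equal(rv$truth$csi_surface$depth[fc[1], fc[2]] -
                 rv$truth$rpe_surface$depth[fc[1], fc[2]], 92)
  expect_equal(rv$truth$transition_surface$depth[fc[1], fc[2]] -
                 rv$truth$rpe_surface$depth[fc[1], fc[2]], 20)
})

test_that("ground-truth surfaces are strictly ordered everywhere", {
  for (s in 1:3) {
    tr <- speckled_eye(s)$truth
    expect_true(all(tr$rpe_surface$depth < tr$transition_surface$depth))
    expect_true(all(tr$transition_surface$depth < tr$csi_surface$depth))
    expect_true(all(tr$csi_surface$valid))
  }
})

test_that("the vessel layer is darker than the sclera (lumens are dark)", {
  for (s in 1:5) {
    rv <- speckled_eye(s)
    v <- rv$volume$intensity
    tr <- rv$truth
    nz <- dim(v)[1]
    zg <- array(seq_len(nz) - 1, dim(v))
    rpe <- aperm(array(tr$rpe_surface$depth, c(dim(v)[2:3], nz)), c(3, 1, 2))
    csi <- aperm(array(tr$csi_surface$depth, c(dim(v)[2:3], nz)), c(3, 1, 2))
    in_cv <- zg > rpe + tr$true_cc_levels + 1 & zg < csi - 2
    in_scl <- zg > csi + 2
    expect_lt(mean(v[in_cv]), mean(v[in_scl]))
  }
})

test_that("rendering is bit-reproducible from its seed", {
  row <- eye_row_levels()
  a <- render_volume(row, render_params(), seed = 12)
  b <- render_volume(row, render_params(), seed = 12)
  c <- render_volume(row, render_params(), seed = 13)
  expect_identical(a$volume$intensity, b$volume$intensity)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$volume$intensity, c$volume$intensity))
})

test_that("a choroid that does not fit the axial grid is rejected", {
  row <- eye_row_levels(tc_levels = 170, cc_levels = 20)
  expect_error(render_volume(row, render_params(nz = 192), seed = 1),
               class = "enfacechoroid_error_choroid_overflow")
})

test_that("render_subject honours the two-realization seeding contract", {
  co <- sample_cohort(cohort_spec(n_young = 1, n_old = 0, seed = 8))
  # same noise seed for both realizations, no shift: identical volumes
  rend <- render_subject(co[1:2, ], render_params(), seed = 3,
                         shift_max = 0, realization_seeds = c(55, 55))
  expect_identical(rend$OD$realizations[[1]]$intensity,
                   rend$OD$realizations[[2]]$intensity)
  expect_identical(rend$OD$shift, 0L)
  # default seeds: independent speckle
  rend2 <- render_subject(co[1:2, ], render_params(), seed = 3, shift_max = 0)
  expect_false(identical(rend2$OD$realizations[[1]]$intensity,
                         rend2$OD$realizations[[2]]$intensity))
})

test_that("fellow eyes of a degenerate subject share ground-truth levels", {
  spec <- cohort_spec(n_young = 1, n_old = 0, tc_young = c(379.4, 0),
                      cc_young = c(81.2, 0), inter_eye_corr = 1, seed = 4)
  co <- sample_cohort(spec)
  rend <- render_subject(co[1:2, ], render_params(), seed = 6)
  expect_identical(rend$OD$truth$true_tc_levels, rend$OS$truth$true_tc_levels)
  expect_identical(rend$OD$truth$true_cc_levels, rend$OS$truth$true_cc_levels)
})

test_that("an axial shift between realizations is recovered by the merge", {
  co <- sample_cohort(cohort_spec(n_young = 1, n_old = 0, seed = 21))
  rend <- render_subject(co[1:2, ], render_params(), seed = 9, shift_max = 5)
  od <- rend$OD
  m <- merge_volumes(od$realizations[[1]], od$realizations[[2]])
  lags <- attr(m, "merge_lags")
  expect_equal(as.integer(names(which.max(table(lags)))), -od$shift)
  expect_gt(mean(lags == -od$shift), 0.9)
})
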