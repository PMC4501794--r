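# Plane texture features and CC/CV transition + CSI detection.

test_that("a uniform plane has no dark structure", {
  roi <- roi_mask(c(40, 40), c(20, 20), 0.5, 30)
  f <- compute_plane_features(matrix(0.7, 40, 40), matrix(TRUE, 40, 40), roi)
  expect_equal(f$dark_fraction, 0)
  expect_equal(f$fine_fraction, 0)
  expect_equal(f$coarse_fraction, 0)
})

test_that("one large dark disk is classified entirely coarse", {
  p <- matrix(1, 60, 60)
  yy <- row(p); xx <- col(p)
  p[(yy - 30)^2 + (xx - 30)^2 <= 100] <- 0.05  # diameter 20 px
  roi <- roi_mask(c(60, 60), c(30, 30), 0.8, 30)
  f <- compute_plane_features(p, matrix(TRUE, 60, 60), roi)
  expect_gt(f$dark_fraction, 0)
  expect_equal(f$coarse_fraction, 1)
  expect_equal(f$fine_fraction, 0)
})

test_that("ROI masks use the stated anatomical radii", {
  m <- roi_mask(c(400, 400), c(200, 200), 3.0, 30)   # 6 mm macular circle
  expect_equal(sum(m), sum((row(m) - 200)^2 + (col(m) - 200)^2 <= 100^2))
  f <- roi_mask(c(64, 64), c(32, 32), 0.5, 30)       # 1 mm foveal circle
  expect_true(f[32, 32])
  expect_false(f[32, 32 + 17])
  expect_error(compute_plane_features(matrix(1, 4, 4), matrix(TRUE, 4, 4),
                                      matrix(FALSE, 4, 4)),
               class = "enfacechoroid_error_empty_roi")
})

test_that("CC planes read fine-dominated and deep CV planes coarse-dominated", {
  for (s in 1:5) {
    ae <- analysed_eye(s)
    pr <- ae$profiles
    cc_mid <- round(ae$truth$true_cc_levels / 2) + 1
    cv_deep <- round((ae$truth$true_cc_levels + ae$truth$true_tc_levels) / 2)
    rcc <- pr[pr$offset == cc_mid, ]
    rcv <- pr[pr$offset == cv_deep, ]
    expect_gt(rcc$fine_fraction, rcc$coarse_fraction)
    expect_gt(rcv$coarse_fraction, rcv$fine_fraction)
  }
})

test_that("step-function profiles give the textbook crossing and CSI", {
  pr <- step_profiles(n = 100, transition = 20, csi = 92, dark = 0.3)
  tr <- detect_transition(pr)
  expect_identical(tr$level, 20L)
  expect_false(tr$low_confidence)
  cs <- detect_csi(pr, tr$level)
  expect_identical(cs$level, 92L)
  expect_false(cs$low_confidence)
})

test_that("monotone no-crossing input falls back with a low-confidence flag", {
  pr <- step_profiles(n = 30, transition = 40, dark = 0.4)  # never crosses
  tr <- detect_transition(pr)
  expect_true(tr$low_confidence)
  expect_true(tr$level >= 1 && tr$level <= 30)
})

test_that("a stack truncated above the CSI raises a hard failure", {
  pr <- step_profiles(n = 50, transition = 20, dark = 0.3)  # vessels persist
  expect_error(detect_csi(pr, 20L), class = "enfacechoroid_error_csi_not_found")
  expect_error(detect_transition(step_profiles(n = 3)),
               class = "enfacechoroid_error_bad_params")
})

test_that("boundary recovery on rendered eyes is within two levels", {
  errs_tr <- c(); errs_cs <- c()
  for (s in 1:5) {
    ae <- analysed_eye(s)
    tr <- detect_transition(ae$profiles)
    cs <- detect_csi(ae$profiles, tr$level)
    expect_true(0 < tr$level && tr$level < cs$level)
    errs_tr <- c(errs_tr, tr$level - ae$truth$true_cc_levels)
    errs_cs <- c(errs_cs, cs$level - ae$truth$true_tc_levels)
  }
  expect_lte(max(abs(errs_tr)), 2)
  expect_lte(max(abs(errs_cs)), 2)
})

test_that("detection is deterministic given a stack", {
  ae <- analysed_eye(1)
  p1 <- plane_profiles(ae$stack, ae$truth$fovea_center, boundary_params(),
                       exclude = ae$shadow)
  p2 <- plane_profiles(ae$stack, ae$truth$fovea_center, boundary_params(),
                       exclude = ae$shadow)
  expect_identical(p1, p2)
  expect_identical(detect_transition(p1), detect_transition(p2))
})

test_that("perturbing the lumen threshold leaves no systematic boundary shift", {
  # synthetic two-observer jitter: alpha +/- 20%
  tc <- function(alpha_scale) {
    vapply(1:5, function(s) {
      ae <- analysed_eye(s)
      bp <- boundary_params()
      bp$alpha <- bp$alpha * alpha_scale
      pr <- plane_profiles(ae$stack, ae$truth$fovea_center, bp,
                           exclude = ae$shadow)
      tr <- detect_transition(pr, bp)
      detect_csi(pr, tr$level, bp)$level
    }, numeric(1))
  }
  ba <- bland_altman(cbind(tc(1.2), tc(0.8)))
  expect_lte(abs(ba$bias), 1)
})
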