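# RPE surface detection and surface regularization.

test_that("score_ascan localises an isolated bright plane and flags degeneracy", {
  prof <- rep(0.1, 80)
  prof[41] <- 1  # z = 40 (0-based)
  s <- score_ascan(prof)
  expect_equal(which.max(s) - 1, 40)
  expect_false(attr(s, "low_confidence"))
  s0 <- score_ascan(rep(0.5, 80))
  expect_true(attr(s0, "low_confidence"))
  expect_true(all(s0 == 0))
  expect_error(score_ascan(1:5), class = "enfacechoroid_error_bad_params")
})

test_that("per-A-scan scores peak inside the true RPE band on a noise-free volume", {
  rv <- noise_free_eye()
  v <- rv$volume$intensity
  hits <- 0; total <- 0
  for (y in seq(1, 64, by = 9)) for (x in seq(1, 64, by = 9)) {
    s <- score_ascan(v[, y, x])
    err <- abs((which.max(s) - 1) - rv$truth$rpe_surface$depth[y, x])
    total <- total + 1
    hits <- hits + (err <= 1.5)  # band half-width
  }
  expect_gte(hits / total, 0.99)
})

test_that("a noise-free flat RPE is recovered exactly", {
  rv <- noise_free_eye()
  surf <- segment_rpe(rv$volume)
  expect_true(all(surf$valid))
  expect_equal(surf$depth, rv$truth$rpe_surface$depth, tolerance = 1e-12)
})

test_that("surface error stays small under default speckle", {
  rms <- vapply(1:5, function(s) {
    rv <- speckled_eye(s)
    surf <- segment_rpe(rv$volume)
    sqrt(mean((surf$depth - rv$truth$rpe_surface$depth)^2))
  }, numeric(1))
  expect_true(all(rms <= 1.5))
})

test_that("shadowed A-scans are inpainted with small error", {
  co <- sample_cohort(cohort_spec(n_young = 1, n_old = 0, seed = 61))
  rp <- render_params(n_shadows = 10, shadow_attenuation = 0.1)
  rv <- render_volume(co[1, ], rp, seed = 62)
  surf <- segment_rpe(rv$volume)
  sh <- rv$truth$shadow_mask
  expect_gt(sum(sh), 0)
  err <- abs(surf$depth - rv$truth$rpe_surface$depth)
  expect_lte(mean(err[sh]), 2.5)
  expect_true(all(surf$valid))
})

test_that("surface error degrades monotonically with speckle variance", {
  co <- sample_cohort(cohort_spec(n_young = 1, n_old = 0, seed = 71))
  rms_at <- function(k) {
    mean(vapply(1:3, function(s) {
      rv <- render_volume(co[1, ], render_params(speckle_k = k), seed = 80 + s)
      surf <- segment_rpe(rv$volume)
      sqrt(mean((surf$depth - rv$truth$rpe_surface$depth)^2))
    }, numeric(1)))
  }
  errs <- c(rms_at(Inf), rms_at(8), rms_at(2))
  expect_true(all(diff(errs) >= -0.05))  # non-decreasing up to MC jitter
})

test_that("regularize_surface is an idempotent outlier filter", {
  set.seed(5)
  yy <- row(matrix(0, 40, 40)); xx <- col(matrix(0, 40, 40))
  smooth <- 50 + 0.01 * (yy - 20)^2 + 0.008 * (xx - 20)^2
  # smooth surface: fixed point
  s1 <- regularize_surface(surface_map(smooth))
  expect_equal(s1$depth, smooth, tolerance = 1e-12)
  # single spike is replaced by its neighbourhood
  spiked <- smooth; spiked[17, 23] <- spiked[17, 23] + 20
  s2 <- regularize_surface(surface_map(spiked))
  expect_lte(abs(s2$depth[17, 23] - median(smooth[15:19, 21:25])), 1)
  # idempotence
  s3 <- regularize_surface(s2)
  expect_equal(s3$depth, s2$depth, tolerance = 1e-12)
})

test_that("30% missing entries on a quadratic surface reconstruct within 1 px RMS", {
  set.seed(9)
  yy <- row(matrix(0, 50, 50)); xx <- col(matrix(0, 50, 50))
  truth <- 60 + 0.012 * (yy - 25)^2 + 0.01 * (xx - 25)^2
  valid <- matrix(runif(2500) > 0.3, 50, 50)
  s <- regularize_surface(surface_map(truth, valid = valid))
  expect_true(all(s$valid))
  expect_lte(sqrt(mean((s$depth - truth)^2)), 1)
})

test_that("a volume with mostly degenerate A-scans is rejected as unusable", {
  rv <- noise_free_eye()
  v <- rv$volume
  d <- dim(v$intensity)
  m <- matrix(v$intensity, d[1])
  kill <- seq_len(ncol(m)) <= 0.6 * ncol(m)
  m[, kill] <- 0.5  # constant profiles carry no surface information
  v$intensity <- array(m, d)
  expect_error(segment_rpe(v), class = "enfacechoroid_error_volume_unusable")
})
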