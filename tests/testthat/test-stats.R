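# Pooled t-tests, ICC(A,1)/(C,1), Bland-Altman, and the group report.

test_that("identical summaries give the null result", {
  g <- group_summary(10, 50, 5)
  r <- pooled_ttest_from_summaries(g, g)
  expect_equal(r$t, 0)
  expect_equal(r$p_two_sided, 1)
  expect_equal(r$df, 18)
})

test_that("published group summaries reproduce the printed p-values", {
  p_tc <- pooled_ttest_from_summaries(group_summary(14, 379.4, 72.0),
                                      group_summary(12, 305.0, 51.5))$p_two_sided
  p_cc <- pooled_ttest_from_summaries(group_summary(14, 81.2, 17.0),
                                      group_summary(12, 56.4, 11.8))$p_two_sided
  p_cv <- pooled_ttest_from_summaries(group_summary(14, 298.1, 60.0),
                                      group_summary(12, 248.6, 50.1))$p_two_sided
  expect_equal(round(p_tc, 3), 0.006)
  expect_equal(round(p_cc, 4), 0.0003)
  expect_equal(round(p_cv, 2), 0.03)
})

test_that("raw-value test equals the summary formula to machine precision", {
  set.seed(14)
  for (i in 1:20) {
    a <- rnorm(sample(3:30, 1), 10, 2)
    b <- rnorm(sample(3:30, 1), 11, 3)
    r1 <- pooled_ttest(a, b)
    r2 <- pooled_ttest_from_summaries(
      group_summary(length(a), mean(a), sd(a)),
      group_summary(length(b), mean(b), sd(b)))
    expect_equal(r1$t, r2$t, tolerance = 1e-12)
    expect_equal(r1$p_two_sided, r2$p_two_sided, tolerance = 1e-12)
    # swapping groups flips t, keeps p
    r3 <- pooled_ttest(b, a)
    expect_equal(r3$t, -r1$t, tolerance = 1e-12)
    expect_equal(r3$p_two_sided, r1$p_two_sided, tolerance = 1e-12)
  }
  expect_error(pooled_ttest(1, 1:5), class = "enfacechoroid_error_bad_params")
})

test_that("the t-test holds its nominal type-I error", {
  set.seed(2024)
  rej <- mean(vapply(1:1000, function(i) {
    pooled_ttest(rnorm(13, 100, 15), rnorm(13, 100, 15))$p_two_sided <= 0.05
  }, logical(1)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("degenerate zero-variance summaries are flagged", {
  r <- pooled_ttest_from_summaries(group_summary(5, 10, 0), group_summary(5, 12, 0))
  expect_true(r$degenerate)
  expect_equal(r$p_two_sided, 0)
  r0 <- pooled_ttest_from_summaries(group_summary(5, 10, 0), group_summary(5, 10, 0))
  expect_false(r0$degenerate)
  expect_equal(r0$p_two_sided, 1)
})

test_that("ICC matches an independent reference implementation", {
  # two-rater fixture; expected values computed with an independent
  # two-way ANOVA ICC implementation (absolute agreement and consistency,
  # single measures) and frozen here
  r1 <- c(334.8, 376.4, 164.4, 251.7, 245.2, 355.5, 347.2, 355.7, 287.9,
          300.2, 326.9, 304.4)
  r2 <- c(362.4, 388.3, 176.4, 290.5, 268.0, 343.7, 352.7, 360.8, 282.8,
          290.0, 299.0, 272.5)
  a <- icc_agreement(cbind(r1, r2))
  expect_equal(a$icc, 0.937782, tolerance = 1e-6)
  expect_equal(a$ci_low, 0.80, tolerance = 0.005)
  expect_equal(a$ci_high, 0.98, tolerance = 0.005)
  cns <- icc_agreement(cbind(r1, r2), form = "consistency")
  expect_equal(cns$icc, 0.933877, tolerance = 1e-6)
})

test_that("ICC edge cases: perfect agreement, degeneracy, small n", {
  x <- c(1, 5, 9, 13, 2.5, 7)
  perfect <- icc_agreement(cbind(x, x))
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$ci_low, 1)
  zero <- icc_agreement(cbind(rep(3, 6), rep(3, 6)))
  expect_true(zero$degenerate)
  expect_error(icc_agreement(cbind(1:3, 2:4)),
               class = "enfacechoroid_error_bad_params")
})

test_that("ICC recovers the analytic intraclass correlation", {
  set.seed(77)
  sigma_s <- 10; sigma_e <- 6
  rho <- sigma_s^2 / (sigma_s^2 + sigma_e^2)
  subj <- rnorm(500, 50, sigma_s)
  pairs <- cbind(subj + rnorm(500, 0, sigma_e), subj + rnorm(500, 0, sigma_e))
  expect_lt(abs(icc_agreement(pairs)$icc - rho), 0.1)
})

test_that("the ICC confidence interval has near-nominal coverage", {
  set.seed(88)
  rho <- 0.95
  sigma_s <- sqrt(rho); sigma_e <- sqrt(1 - rho)
  cover <- mean(vapply(1:500, function(i) {
    subj <- rnorm(26, 0, sigma_s)
    a <- icc_agreement(cbind(subj + rnorm(26, 0, sigma_e),
                             subj + rnorm(26, 0, sigma_e)))
    a$ci_low <= rho && rho <= a$ci_high
  }, logical(1)))
  expect_gte(cover, 0.9)
})

test_that("ICC decreases as rater noise grows", {
  set.seed(99)
  subj <- rnorm(200, 0, 10)
  icc_at <- function(s) {
    icc_agreement(cbind(subj + rnorm(200, 0, s), subj + rnorm(200, 0, s)))$icc
  }
  iccs <- c(icc_at(1), icc_at(5), icc_at(15))
  expect_true(all(diff(iccs) < 0))
  expect_true(all(iccs <= 1))
})

test_that("Bland-Altman recovers constant offsets and known distributions", {
  x <- c(10, 20, 30, 40)
  b0 <- bland_altman(cbind(x, x))
  expect_equal(b0$bias, 0)
  expect_equal(b0$loa_low, 0)
  expect_equal(b0$loa_high, 0)
  b5 <- bland_altman(cbind(x, x + 5))
  expect_equal(b5$bias, -5)
  expect_equal(b5$sd_diff, 0)
  set.seed(55)
  y <- rnorm(1000, 100, 20)
  ba <- bland_altman(cbind(y + rnorm(1000, 2, 3), y))
  expect_lt(abs(ba$bias - 2), 0.3)
  expect_lt(abs(ba$loa_high - (2 + 5.88)), 0.5)
  expect_lt(abs(ba$loa_low - (2 - 5.88)), 0.5)
  # width identity is exact
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)
  expect_error(bland_altman(cbind(1, 2)), class = "enfacechoroid_error_bad_params")
})

test_that("group_compare_report emits the five-metric table", {
  co <- sample_cohort(cohort_spec(n_young = 14, n_old = 12, seed = 10))
  rec <- co |>
    dplyr::group_by(subject_id) |>
    dplyr::summarize(group = dplyr::first(group),
                     tc_um = mean(tc_um), cc_um = mean(cc_um),
                     cv_um = mean(tc_um - cc_um),
                     cc_pct = mean(100 * cc_um / tc_um),
                     cv_pct = 100 - cc_pct, .groups = "drop")
  rep <- group_compare_report(rec)
  expect_identical(rep$metric, c("tc_um", "cc_um", "cv_um", "cc_pct", "cv_pct"))
  expect_true(all(rep$p_value > 0 & rep$p_value <= 1))
  expect_identical(rep$df, rep(24, 5))
  expect_error(group_compare_report(rec[rec$group == "young", ]),
               class = "enfacechoroid_error_bad_params")
})

test_that("a constant group shift with zero variance is flagged, direction kept", {
  rec <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:6),
    group = rep(c("young", "old"), each = 3),
    tc_um = rep(c(380, 300), each = 3),
    cc_um = rep(c(80, 56), each = 3),
    cv_um = rep(c(300, 244), each = 3),
    cc_pct = rep(c(21, 19), each = 3),
    cv_pct = rep(c(79, 81), each = 3)
  )
  rep <- group_compare_report(rec)
  expect_true(all(rep$degenerate[rep$metric %in% c("tc_um", "cc_um", "cv_um")]))
  expect_true(all(rep$mean_young[1:3] > rep$mean_old[1:3]))
})

test_that("group differences become uniformly significant at tenfold n", {
  set.seed(123)
  sig <- vapply(1:100, function(i) {
    co <- sample_cohort(cohort_spec(n_young = 140, n_old = 120,
                                    seed = 1000 + i))
    rec <- co |>
      dplyr::group_by(subject_id) |>
      dplyr::summarize(group = dplyr::first(group),
                       tc_um = mean(tc_um), cc_um = mean(cc_um),
                       cv_um = mean(tc_um - cc_um), .groups = "drop")
    rep <- group_compare_report(rec, metrics = c("tc_um", "cc_um", "cv_um"))
    all(rep$p_value <= 0.05)
  }, logical(1))
  expect_gte(mean(sig), 0.95)
})

test_that("tidy methods return one-row tibbles with the estimates", {
  tt <- tidy(pooled_ttest(c(1, 2, 3), c(4, 5, 7)))
  expect_s3_class(tt, "tbl_df")
  expect_identical(nrow(tt), 1L)
  ti <- tidy(icc_agreement(cbind(1:6, c(1.1, 2, 3.2, 4, 5, 6))))
  expect_true(all(c("estimate", "conf.low", "conf.high") %in% names(ti)))
  tb <- tidy(bland_altman(cbind(1:5, 2:6)))
  expect_equal(tb$bias, -1)
})
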