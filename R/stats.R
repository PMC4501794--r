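# Statistical layer: classic pooled-variance unpaired t-tests (computable
# from raw values or from printed group summaries), two-way random-effects
# absolute-agreement single-measures ICC with F-based 95% CI, Bland-Altman
# limits of agreement, and the group-comparison report. Significance is
# assessed at the 5% level; no multiple-testing correction is applied.

#' Group summary (n, mean, SD)
#'
#' @param n group size (>= 2).
#' @param mean,sd sample mean and standard deviation.
#' @param label optional group label.
#' @return A list of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd, label = NA_character_) {
  if (n < 2) stop_enface("bad_params", "group size must be >= 2.")
  if (sd < 0) stop_enface("bad_params", "SD must be >= 0.")
  structure(list(n = as.integer(n), mean = as.numeric(mean),
                 sd = as.numeric(sd), label = label),
            class = "group_summary")
}

#' Pooled-variance unpaired t-test from group summaries
#'
#' The classic Student test: `sp^2 = ((n1-1)s1^2 + (n2-1)s2^2)/(n1+n2-2)`,
#' `t = (m1-m2)/(sp * sqrt(1/n1 + 1/n2))`, two-sided p at `df = n1+n2-2`.
#' This is the test that reproduces published group-comparison p-values
#' from printed n/mean/SD alone.
#'
#' @param a,b [group_summary()] objects (or lists with `n`, `mean`, `sd`).
#' @return A list of class `pooled_ttest`: `t`, `df`, `p_two_sided`,
#'   `mean_difference`, `degenerate` (TRUE when the pooled SD is zero).
#' @examples
#' # younger vs older total choroidal thickness, from printed summaries
#' tidy(pooled_ttest_from_summaries(group_summary(14, 379.4, 72.0),
#'                                  group_summary(12, 305.0, 51.5)))
#' @export
pooled_ttest_from_summaries <- function(a, b) {
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  md <- a$mean - b$mean
  degenerate <- FALSE
  if (sp2 <= 0) {
    degenerate <- md != 0
    t <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    t <- md / sqrt(sp2 * (1 / a$n + 1 / b$n))
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p_two_sided = p, mean_difference = md,
                 degenerate = degenerate),
            class = "pooled_ttest")
}

#' Pooled-variance unpaired t-test from raw values
#'
#' Identical, to machine precision, to [pooled_ttest_from_summaries()]
#' applied to the two samples' summaries.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return A `pooled_ttest` (see [pooled_ttest_from_summaries()]).
#' @export
pooled_ttest <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop_enface("bad_params", "each sample needs at least 2 values.")
  }
  pooled_ttest_from_summaries(
    group_summary(length(values_a), mean(values_a), sd(values_a)),
    group_summary(length(values_b), mean(values_b), sd(values_b))
  )
}

#' @export
print.pooled_ttest <- function(x, ...) {
  cat(sprintf("Pooled t-test: t = %.3f, df = %d, p = %.4g (diff %.2f)\n",
              x$t, x$df, x$p_two_sided, x$mean_difference))
  invisible(x)
}

#' @export
tidy.pooled_ttest <- function(x, ...) {
  tibble(estimate = x$mean_difference, statistic = x$t, df = x$df,
         p.value = x$p_two_sided, method = "pooled unpaired t",
         degenerate = x$degenerate)
}

#' Intraclass correlation for two-rater agreement
#'
#' ICC(A,1): two-way random effects, absolute agreement, single measures,
#' computed from the mean squares of the subject-by-rater layout, with the
#' 95% confidence interval from the McGraw-Wong F bounds. The consistency
#' form ICC(C,1) is available via `form = "consistency"`.
#'
#' @param pairs two-column numeric matrix or data frame, one row per
#'   subject, columns the two raters (>= 5 rows).
#' @param form `"agreement"` (default) or `"consistency"`.
#' @param conf_level confidence level of the interval.
#' @return A list of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `model`, `n`, `degenerate`.
#' @export
icc_agreement <- function(pairs, form = c("agreement", "consistency"),
                          conf_level = 0.95) {
  form <- match.arg(form)
  m <- as.matrix(pairs)
  if (ncol(m) != 2L) stop_enface("bad_params", "pairs must have two columns.")
  if (nrow(m) < 5L) stop_enface("bad_params", "need at least 5 pairs.")
  if (anyNA(m)) stop_enface("bad_params", "pairs contain missing values.")
  n <- nrow(m); k <- 2L
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  SST <- sum((m - grand)^2)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SSE <- max(0, SST - SSR - SSC)
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  if (SST <= 0) {
    return(structure(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          model = form, n = n, degenerate = TRUE),
                     class = "icc_result"))
  }
  alpha <- 1 - conf_level
  if (form == "agreement") {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
    if (1 - icc < 1e-12) {
      lo <- hi <- 1
    } else {
      a <- (k * icc) / (n * (1 - icc))
      b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
      v <- (a * MSC + b * MSE)^2 /
        ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
      FL <- qf(1 - alpha / 2, n - 1, v)
      FU <- qf(1 - alpha / 2, v, n - 1)
      lo <- n * (MSR - FL * MSE) /
        (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
      hi <- n * (FU * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    }
  } else {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    if (1 - icc < 1e-12) {
      lo <- hi <- 1
    } else {
      Fv <- MSR / MSE
      FL <- Fv / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      FU <- Fv * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (FL - 1) / (FL + k - 1)
      hi <- (FU - 1) / (FU + k - 1)
    }
  }
  structure(list(icc = icc, ci_low = min(lo, icc), ci_high = max(hi, icc),
                 model = form, n = n, degenerate = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s, single measures) = %.3f (95%% CI %.3f-%.3f), n = %d\n",
              if (x$model == "agreement") "A,1" else "C,1",
              x$icc, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' @export
tidy.icc_result <- function(x, ...) {
  tibble(estimate = x$icc, conf.low = x$ci_low, conf.high = x$ci_high,
         model = x$model, n = x$n, degenerate = x$degenerate)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d_i = x_i - y_i`; bias = mean(d), limits of agreement =
#' bias +/- 1.96 sd(d).
#'
#' @param pairs two-column numeric matrix or data frame (>= 2 rows).
#' @return A list of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n_pairs`, plus the per-pair `means` and `diffs` used by
#'   [autoplot.bland_altman()].
#' @export
bland_altman <- function(pairs) {
  m <- as.matrix(pairs)
  if (ncol(m) != 2L) stop_enface("bad_params", "pairs must have two columns.")
  if (nrow(m) < 2L) stop_enface("bad_params", "need at least 2 pairs.")
  d <- m[, 1] - m[, 2]
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n_pairs = nrow(m),
                 means = rowMeans(m), diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n_pairs))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high, n = x$n_pairs)
}

#' Group-comparison report across thickness metrics
#'
#' For each of TC, CC, CV (um) and CC%, CV%: group means and SDs of the
#' subject-averaged values, and the pooled unpaired t-test between the
#' younger and older groups.
#'
#' @param subjects tibble of subject records (one row per subject, columns
#'   `group` plus the metrics), as produced by [average_eyes()] rows bound
#'   together or by [run_pipeline()].
#' @param metrics character vector of metric columns to compare.
#' @return A tibble with one row per metric: `mean_young`, `sd_young`,
#'   `n_young`, `mean_old`, `sd_old`, `n_old`, `t`, `df`, `p_value`,
#'   `degenerate`.
#' @export
group_compare_report <- function(subjects,
                                 metrics = c("tc_um", "cc_um", "cv_um",
                                             "cc_pct", "cv_pct")) {
  g <- split(subjects, subjects$group)
  if (!all(c("young", "old") %in% names(g))) {
    stop_enface("bad_params", "both groups must be non-empty.")
  }
  if (any(vapply(g, nrow, integer(1)) < 2L)) {
    stop_enface("bad_params", "each group needs at least 2 subjects.")
  }
  purrr::map_dfr(metrics, function(mname) {
    ya <- g$young[[mname]]; ol <- g$old[[mname]]
    tt <- pooled_ttest(ya, ol)
    tibble(
      metric = mname,
      mean_young = mean(ya), sd_young = sd(ya), n_young = length(ya),
      mean_old = mean(ol), sd_old = sd(ol), n_old = length(ol),
      t = tt$t, df = tt$df, p_value = tt$p_two_sided,
      degenerate = tt$degenerate
    )
  })
}
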