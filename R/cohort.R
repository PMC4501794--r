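# Cohort simulation. Per-group subfoveal thickness distributions default to
# the published normal-aging reference values (younger < 40 y vs older
# >= 40 y): TC 379.4 +/- 72.0 vs 305.0 +/- 51.5 um, CC 81.2 +/- 17.0 vs
# 56.4 +/- 11.8 um, with a high inter-eye correlation.

#' Specify a two-group, two-eye cohort
#'
#' Defaults emulate a normal-aging study cohort: 14 younger (< 40 years) and
#' 12 older (>= 40 years) subjects with group-wise subfoveal total choroidal
#' (TC) and choroidal-microvasculature (CC) thickness means/SDs in
#' micrometres and strongly correlated fellow eyes.
#'
#' @param n_young,n_old subject counts per group.
#' @param tc_young,tc_old,cc_young,cc_old length-2 numeric `c(mean, sd)` of
#'   the group thickness distributions, micrometres.
#' @param inter_eye_corr correlation between fellow-eye thicknesses, in
#'   `[0, 1]`.
#' @param age_young,age_old length-2 numeric age ranges (years).
#' @param tc_max_um upper truncation of the total choroidal thickness
#'   (default 600 um): eyes whose choroid exceeds the instrument's usable
#'   axial window are not analysable and are redrawn. A > 3-sigma tail
#'   event under the default distributions.
#' @param seed integer seed making the cohort fully reproducible.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_young = 14L, n_old = 12L,
                        tc_young = c(379.4, 72.0), tc_old = c(305.0, 51.5),
                        cc_young = c(81.2, 17.0), cc_old = c(56.4, 11.8),
                        inter_eye_corr = 0.95,
                        age_young = c(24, 40), age_old = c(42, 66),
                        tc_max_um = 600,
                        seed = 1L) {
  spec <- list(
    n_young = as.integer(n_young), n_old = as.integer(n_old),
    tc_young = as.numeric(tc_young), tc_old = as.numeric(tc_old),
    cc_young = as.numeric(cc_young), cc_old = as.numeric(cc_old),
    inter_eye_corr = as.numeric(inter_eye_corr),
    age_young = as.numeric(age_young), age_old = as.numeric(age_old),
    tc_max_um = as.numeric(tc_max_um),
    seed = as.integer(seed)
  )
  for (g in c("young", "old")) {
    tc <- spec[[paste0("tc_", g)]]; cc <- spec[[paste0("cc_", g)]]
    if (tc[1] <= 0 || cc[1] <= 0 || tc[2] < 0 || cc[2] < 0) {
      stop_enface("bad_spec", "thickness means must be > 0 and SDs >= 0.")
    }
    if (cc[1] >= tc[1]) {
      stop_enface("bad_spec",
                  sprintf("infeasible spec: %s CC mean (%.1f) >= TC mean (%.1f).",
                          g, cc[1], tc[1]))
    }
    if (tc[1] >= spec$tc_max_um) {
      stop_enface("bad_spec",
                  sprintf("infeasible spec: %s TC mean (%.1f) >= tc_max_um (%.1f).",
                          g, tc[1], spec$tc_max_um))
    }
  }
  if (spec$inter_eye_corr < 0 || spec$inter_eye_corr > 1) {
    stop_enface("bad_spec", "inter_eye_corr must lie in [0, 1].")
  }
  structure(spec, class = "cohort_spec")
}

# minimum admissible layer thickness: 4 axial pixels
.min_layer_um <- 4 * 4.13

#' Sample per-subject, per-eye ground-truth thicknesses
#'
#' Each subject draws a latent thickness per metric from the group
#' distribution; fellow eyes share the latent value plus independent
#' eye-level noise scaled so that the fellow-eye correlation equals
#' `inter_eye_corr`. Draws violating the positivity floor (CC and CV = TC -
#' CC each at least four axial pixels, 16.52 um) are redrawn; with the
#' default parameters this is a > 3-sigma tail event.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with one row per eye: `subject_id`, `group`,
#'   `age_years`, `eye`, `tc_um`, `cc_um`.
#' @examples
#' sample_cohort(cohort_spec(n_young = 2, n_old = 2, seed = 7))
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rho <- spec$inter_eye_corr
  draw_subject <- function(tc_ms, cc_ms) {
    # latent + eye noise; Var(latent) = rho * sigma^2 so corr(OD, OS) = rho
    repeat {
      tc_l <- rnorm(1, tc_ms[1], tc_ms[2] * sqrt(rho))
      cc_l <- rnorm(1, cc_ms[1], cc_ms[2] * sqrt(rho))
      tc <- tc_l + rnorm(2, 0, tc_ms[2] * sqrt(1 - rho))
      cc <- cc_l + rnorm(2, 0, cc_ms[2] * sqrt(1 - rho))
      if (all(cc >= .min_layer_um) && all(tc - cc >= .min_layer_um) &&
          all(tc <= spec$tc_max_um)) {
        return(list(tc = tc, cc = cc))
      }
    }
  }
  withr::with_seed(spec$seed, {
    rows <- list()
    groups <- c(rep("young", spec$n_young), rep("old", spec$n_old))
    for (i in seq_along(groups)) {
      g <- groups[i]
      th <- draw_subject(spec[[paste0("tc_", g)]], spec[[paste0("cc_", g)]])
      age <- runif(1, spec[[paste0("age_", g)]][1], spec[[paste0("age_", g)]][2])
      rows[[i]] <- tibble(
        subject_id = sprintf("S%03d", i),
        group = g,
        age_years = age,
        eye = c("OD", "OS"),
        tc_um = th$tc,
        cc_um = th$cc
      )
    }
    dplyr::bind_rows(rows)
  })
}
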