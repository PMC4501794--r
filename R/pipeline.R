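# End-to-end orchestration: simulate -> merge -> segment -> flatten ->
# enface stack -> boundaries -> quantify -> group statistics, fully
# reproducible from one master seed, plus the internal (two-observer
# analogue) and external (B-scan vs enface) validation analyses.

#' Pipeline configuration
#'
#' @param cohort a [cohort_spec()]; its own seed is superseded by the
#'   pipeline master seed.
#' @param render a [render_params()].
#' @param segmentation a [segmentation_params()].
#' @param boundaries a [boundary_params()].
#' @param shift_max maximum |axial shift| (pixels) between the two
#'   acquisitions of an eye, exercising the merge registration.
#' @param seed master seed fixing every downstream random draw.
#' @param keep_stacks keep per-eye enface stacks in the run object (needed
#'   by [validate_internal()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            render = render_params(),
                            segmentation = segmentation_params(),
                            boundaries = boundary_params(),
                            shift_max = 3L,
                            seed = 1L,
                            keep_stacks = TRUE) {
  structure(list(cohort = cohort, render = render,
                 segmentation = segmentation, boundaries = boundaries,
                 shift_max = as.integer(shift_max), seed = as.integer(seed),
                 keep_stacks = isTRUE(keep_stacks)),
            class = "pipeline_config")
}

.shadow_columns <- function(volume, seg) {
  d <- dim(volume$intensity)
  M <- matrix(volume$intensity, d[1L], d[2L] * d[3L])
  energy <- colSums(M * M)
  matrix(energy < seg$shadow_floor * median(energy), d[2L], d[3L])
}

.analyse_eye <- function(merged, truth, cfg) {
  surf <- segment_rpe(merged, cfg$segmentation)
  shadow <- .shadow_columns(merged, cfg$segmentation)
  flat <- flatten_volume(merged, surf)
  nz <- dim(flat$intensity)[1L]
  stack <- extract_enface_stack(flat, c(1L, nz - 1L - flat$reference_level))
  profiles <- plane_profiles(stack, truth$fovea_center, cfg$boundaries,
                             exclude = shadow)
  tr <- detect_transition(profiles, cfg$boundaries)
  cs <- detect_csi(profiles, tr$level, cfg$boundaries)
  b <- structure(list(rpe_level = 0L, transition_level = tr$level,
                      csi_level = cs$level,
                      transition_low_confidence = tr$low_confidence,
                      csi_low_confidence = cs$low_confidence,
                      profiles = profiles),
                 class = "layer_boundary_set")
  list(surface = surf, shadow = shadow, stack = stack, boundaries = b,
       bscan = measure_tc_bscan(merged, surf, truth$fovea_center,
                                cfg$boundaries))
}

#' Run the full enface choroidal analysis pipeline on a synthetic cohort
#'
#' Samples the cohort, renders two speckle realizations per eye, merges
#' them, segments the RPE reference, extracts the enface stack, detects the
#' CC/CV transition and the CSI, quantifies absolute and relative
#' thicknesses per eye, averages fellow eyes, and compares the age groups.
#' Identical `(config, seed)` yields byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, `thickness.csv`,
#'   `subjects.csv`, `table2_like.csv` and `manifest.json` are written.
#' @return A list of class `enface_run`: `cohort` (sampled ground truth),
#'   `thickness` (per-eye enface records), `bscan` (per-eye B-scan TC),
#'   `subjects` (eye-averaged records), `report` (group comparison),
#'   `boundaries` (per-eye detected and true levels), `eyes` (per-eye
#'   stacks and surfaces when `keep_stacks`), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$cohort
  spec$seed <- child_seed(config$seed, 0L)
  cohort <- sample_cohort(spec)
  ids <- unique(cohort$subject_id)
  thickness <- list(); bscan <- list(); bnd <- list(); eyes <- list()
  for (i in seq_along(ids)) {
    rows <- cohort[cohort$subject_id == ids[i], ]
    rend <- tryCatch(
      render_subject(rows, config$render, seed = child_seed(config$seed, i),
                     shift_max = config$shift_max),
      error = function(e) {
        stop_enface("stage_failure",
                    sprintf("render failed for subject %s: %s", ids[i],
                            conditionMessage(e)))
      }
    )
    for (eye in names(rend)) {
      re <- rend[[eye]]
      res <- tryCatch({
        merged <- merge_volumes(re$realizations[[1]], re$realizations[[2]])
        .analyse_eye(merged, re$truth, config)
      }, error = function(e) {
        stop_enface("stage_failure",
                    sprintf("analysis failed for subject %s eye %s: %s",
                            ids[i], eye, conditionMessage(e)))
      })
      row <- rows[rows$eye == eye, ]
      key <- paste(ids[i], eye, sep = "_")
      thickness[[key]] <- quantify_eye(res$boundaries,
                                       subject_id = ids[i], eye = eye,
                                       group = row$group,
                                       age_years = row$age_years)
      bscan[[key]] <- dplyr::mutate(res$bscan, group = row$group)
      bnd[[key]] <- tibble(
        subject_id = ids[i], eye = eye, group = row$group,
        transition_level = res$boundaries$transition_level,
        csi_level = res$boundaries$csi_level,
        true_cc_levels = re$truth$true_cc_levels,
        true_tc_levels = re$truth$true_tc_levels,
        transition_low_confidence = res$boundaries$transition_low_confidence,
        csi_low_confidence = res$boundaries$csi_low_confidence
      )
      eyes[[key]] <- if (config$keep_stacks) {
        list(stack = res$stack, shadow = res$shadow, surface = res$surface,
             truth = re$truth, subject_id = ids[i], eye = eye, group = row$group)
      } else NULL
    }
  }
  thickness <- dplyr::bind_rows(thickness)
  bscan <- dplyr::bind_rows(bscan)
  boundaries <- dplyr::bind_rows(bnd)
  subjects <- purrr::map_dfr(split(thickness, thickness$subject_id),
                             function(d) average_eyes(d[1, ], d[2, ])) |>
    dplyr::arrange(.data$subject_id)
  report <- group_compare_report(subjects)
  run <- structure(list(cohort = cohort, thickness = thickness, bscan = bscan,
                        subjects = subjects, report = report,
                        boundaries = boundaries, eyes = eyes, config = config),
                   class = "enface_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(thickness, file.path(out_dir, "thickness.csv"))
    readr::write_csv(subjects, file.path(out_dir, "subjects.csv"))
    readr::write_csv(report, file.path(out_dir, "table2_like.csv"))
    manifest <- list(
      seed = config$seed,
      config_hash = rlang::hash(config),
      n_subjects = length(ids),
      n_eyes = nrow(thickness),
      package_version = as.character(utils::packageVersion("enfacechoroid")),
      low_confidence_eyes = boundaries$subject_id[
        boundaries$transition_low_confidence | boundaries$csi_low_confidence]
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.enface_run <- function(x, ...) {
  cat(sprintf("<enface_run> %d subjects / %d eyes, seed %d\n",
              nrow(x$subjects), nrow(x$thickness), x$config$seed))
  print(x$report)
  invisible(x)
}

#' @export
glance.enface_run <- function(x, ...) {
  tibble(
    n_subjects = nrow(x$subjects),
    n_eyes = nrow(x$thickness),
    mean_tc_um = mean(x$subjects$tc_um),
    mean_cc_um = mean(x$subjects$cc_um),
    p_tc = x$report$p_value[x$report$metric == "tc_um"],
    p_cc = x$report$p_value[x$report$metric == "cc_um"],
    p_cv = x$report$p_value[x$report$metric == "cv_um"],
    seed = x$config$seed
  )
}

.requantify_run <- function(run, bp) {
  purrr::map_dfr(run$eyes, function(e) {
    profiles <- plane_profiles(e$stack, e$truth$fovea_center, bp,
                               exclude = e$shadow)
    tr <- detect_transition(profiles, bp)
    cs <- detect_csi(profiles, tr$level, bp)
    quantify_eye(list(rpe_level = 0L, transition_level = tr$level,
                      csi_level = cs$level),
                 subject_id = e$subject_id, eye = e$eye, group = e$group)
  })
}

#' Internal validation: two boundary-parameter "observers"
#'
#' Re-detects the boundaries of every eye under a jittered lumen-threshold
#' profile (observer 2: `alpha` scaled by `1 + alpha_jitter`) and computes
#' the inter-observer ICC and Bland-Altman agreement for the absolute TC,
#' CC and CV thicknesses, emulating inter-observer reproducibility without
#' a second human reader.
#'
#' @param run an [run_pipeline()] result with `keep_stacks = TRUE`.
#' @param alpha_jitter relative jitter of `alpha` (default +0.2, i.e. +20%);
#'   0 reproduces observer 1 exactly.
#' @return A tibble with one row per metric (`tc_um`, `cc_um`, `cv_um`):
#'   ICC estimate and CI, Bland-Altman bias and limits of agreement.
#' @export
validate_internal <- function(run, alpha_jitter = 0.2) {
  stopifnot(inherits(run, "enface_run"))
  if (!length(run$eyes) || is.null(run$eyes[[1]])) {
    stop_enface("bad_params", "run was built with keep_stacks = FALSE.")
  }
  bp2 <- run$config$boundaries
  bp2$alpha <- bp2$alpha * (1 + alpha_jitter)
  obs2 <- .requantify_run(run, bp2)
  obs1 <- run$thickness
  stopifnot(identical(obs1$subject_id, obs2$subject_id),
            identical(obs1$eye, obs2$eye))
  purrr::map_dfr(c("tc_um", "cc_um", "cv_um"), function(mname) {
    pairs <- cbind(obs1[[mname]], obs2[[mname]])
    ia <- icc_agreement(pairs)
    ba <- bland_altman(pairs)
    tibble(metric = mname, icc = ia$icc, icc_low = ia$ci_low,
           icc_high = ia$ci_high, icc_degenerate = ia$degenerate,
           bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
           n = ba$n_pairs)
  })
}

#' External validation: B-scan vs enface total choroidal thickness
#'
#' Pairs each eye's TC measured on the horizontal B-scan through the fovea
#' (the cross-sectional standard method) with its enface TC and returns the
#' Bland-Altman agreement.
#'
#' @param run an [run_pipeline()] result.
#' @return A [bland_altman()] object (bscan minus enface differences), with
#'   the pairs tibble attached as attribute `"pairs"`.
#' @export
validate_external <- function(run) {
  stopifnot(inherits(run, "enface_run"))
  enf <- run$thickness
  bs <- run$bscan
  key <- paste(enf$subject_id, enf$eye)
  stopifnot(identical(key, paste(bs$subject_id, bs$eye)))
  ba <- bland_altman(cbind(bs$tc_um, enf$tc_um))
  attr(ba, "pairs") <- tibble(subject_id = enf$subject_id, eye = enf$eye,
                              tc_bscan = bs$tc_um, tc_enface = enf$tc_um)
  ba
}
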