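#' Pipeline configuration
#'
#' Bundles the analysis constants (reliability threshold 0.1, searchlight
#' 7-voxel cubes with step 2 and a 64-voxel minimum, penalty 0.01, width
#' bound 10, 10000 shuffles for faithful runs) with the synthetic-study
#' settings. All constants are overridable.
#'
#' @param seed master seed; every stage derives its seed from it.
#' @param n_shuffles permutation count for the null distributions.
#' @param reliability_threshold voxel-inclusion cutoff.
#' @param searchlight list with `side`, `step`, `min_reliable`.
#' @param penalty_strength,width_max Gaussian fitting controls.
#' @param synthetic a [synthetic_config()]; its seed is overridden by `seed`.
#' @param run_searchlight logical: run the volumetric stage (off by default;
#'   it simulates its own volume and dominates runtime).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1, n_shuffles = 10000,
                            reliability_threshold = 0.1,
                            searchlight = list(side = 7, step = 2,
                                               min_reliable = 64),
                            penalty_strength = 0.01, width_max = 10,
                            synthetic = synthetic_config(),
                            run_searchlight = FALSE) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (reliability_threshold < -1 || reliability_threshold > 1)
    stop("reliability_threshold must be a correlation value")
  stopifnot(penalty_strength >= 0, width_max > 0)
  synthetic$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed),
                 n_shuffles = as.integer(n_shuffles),
                 reliability_threshold = reliability_threshold,
                 searchlight = searchlight,
                 penalty_strength = penalty_strength,
                 width_max = width_max,
                 synthetic = synthetic,
                 run_searchlight = run_searchlight),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes simulate, reliability screen, templates and similarity profiles
#' (cued and uncued), Gaussian fits, permutation inference (including- and
#' excluding-cue nulls, uncued-path test, cued-versus-uncued contrast),
#' parameter group tests, behavioral summaries, and the brain-behavior
#' correlation. Deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param study optional pre-built study (defaults to
#'   `synthetic_study(config$synthetic)`).
#' @return list of class `"pipeline_report"` with per-stage results and
#'   provenance.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- study %||% synthetic_study(config$synthetic)
  rel <- environment_reliability(study$localizer)
  roi <- conjunction_roi(rel, threshold = config$reliability_threshold)
  if (length(roi) < 2) stop("reliability stage: ROI too small")

  cued <- study_profiles(study, roi = roi, ordering = "cued")
  uncued <- study_profiles(study, roi = roi, ordering = "uncued")

  fits <- fit_participants(cued$profiles,
                           penalty_strength = config$penalty_strength,
                           width_max = config$width_max)

  perm <- list()
  obs_inc <- loo_group_error(cued$profiles, include_cue = TRUE,
                             penalty_strength = config$penalty_strength,
                             width_max = config$width_max)
  null_inc <- shuffled_null(cued$profiles, include_cue = TRUE,
                            n_shuffles = config$n_shuffles,
                            seed = config$seed + 101L,
                            penalty_strength = config$penalty_strength,
                            width_max = config$width_max)
  perm$cued_including_cue <- permutation_result(obs_inc, null_inc)

  obs_exc <- loo_group_error(cued$profiles, include_cue = FALSE,
                             penalty_strength = config$penalty_strength,
                             width_max = config$width_max)
  null_exc <- shuffled_null(cued$profiles, include_cue = FALSE,
                            n_shuffles = config$n_shuffles,
                            seed = config$seed + 102L,
                            penalty_strength = config$penalty_strength,
                            width_max = config$width_max)
  perm$cued_excluding_cue <- permutation_result(obs_exc, null_exc)

  obs_unc <- loo_group_error(uncued$profiles, include_cue = FALSE,
                             penalty_strength = config$penalty_strength,
                             width_max = config$width_max)
  null_unc <- shuffled_null(uncued$profiles, include_cue = FALSE,
                            n_shuffles = config$n_shuffles,
                            seed = config$seed + 103L,
                            penalty_strength = config$penalty_strength,
                            width_max = config$width_max)
  perm$uncued_excluding_cue <- permutation_result(obs_unc, null_unc)

  perm$cued_vs_uncued <- cued_vs_uncued_test(
    cued$profiles, uncued$profiles, n_shuffles = config$n_shuffles,
    seed = config$seed + 104L,
    penalty_strength = config$penalty_strength,
    width_max = config$width_max)

  params <- parameter_group_tests(
    fits, cued$baseline,
    permutation_p = perm$cued_including_cue$p)

  accuracy <- accuracy_vs_chance(study$behavior)
  slopes <- rt_slopes(study$behavior)
  linkage <- brain_behavior_correlation(fits$b, slopes$slope)

  sl <- NULL
  if (isTRUE(config$run_searchlight)) {
    vol_cfg <- config$synthetic
    vol_cfg$n_participants <- min(vol_cfg$n_participants, 8L)
    vol <- simulate_volume(grid_dims = c(12, 12, 12),
                           width_gradient = 0.05, config = vol_cfg)
    maps <- run_searchlight(vol, side = config$searchlight$side,
                            step = config$searchlight$step,
                            min_reliable = config$searchlight$min_reliable,
                            n_shuffles = min(config$n_shuffles, 100L),
                            seed = config$seed + 105L)
    sl <- list(maps = maps,
               width_gradient = within_region_gradient(
                 maps, seq_len(prod(maps$dims)), target = "width"))
  }

  structure(list(config = config, roi_size = length(roi),
                 reliability = rel, profiles_cued = cued,
                 profiles_uncued = uncued, fits = fits,
                 permutation = perm, parameters = params,
                 accuracy = accuracy, rt_slopes = slopes,
                 brain_behavior = linkage, searchlight = sl,
                 provenance = list(seed = config$seed,
                                   n_shuffles = config$n_shuffles,
                                   timestamp = format(Sys.time()))),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("seqgauss pipeline report (seed ", x$config$seed, ")\n", sep = "")
  cat("  ROI size:", x$roi_size, "voxels\n")
  p <- x$permutation
  cat(sprintf("  cued, including cue:  p = %.4g, R^2 = %.4f\n",
              p$cued_including_cue$p, p$cued_including_cue$r_squared))
  cat(sprintf("  cued, excluding cue:  p = %.4g, R^2 = %.4f\n",
              p$cued_excluding_cue$p, p$cued_excluding_cue$r_squared))
  cat(sprintf("  uncued, excluding cue: p = %.4g, R^2 = %.4f\n",
              p$uncued_excluding_cue$p, p$uncued_excluding_cue$r_squared))
  cat(sprintf("  cued vs uncued contrast: p = %.4g\n", p$cued_vs_uncued$p))
  cat(sprintf("  accuracy: %.2f%% (t(%d) = %.2f)\n",
              100 * x$accuracy$mean, x$accuracy$df, x$accuracy$t))
  cat(sprintf("  brain-behavior (asymptote vs RT slope): rho = %.3f\n",
              x$brain_behavior$rho))
  invisible(x)
}
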