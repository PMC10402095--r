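# safe correlation: errors informatively on zero-variance input
corr_or_stop <- function(x, y, what) {
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation (zero variance) for ", what)
  cor(x, y)
}

#' Cue-centered similarity profile for one trial type
#'
#' Correlates a cue-period pattern with the held-out templates of the eight
#' environments on the cued map, arranged by signed circular step from the
#' cue (-4..+4). There are eight distinct correlations; the four-step
#' neighbor is the same environment in both directions, so its value appears
#' at both -4 and +4.
#'
#' @param cue_pattern voxel pattern for the trial type (numeric vector).
#' @param templates matrix `environment x voxel` of held-out templates;
#'   row `e + 1` is environment id `e`.
#' @param path the ordering used to arrange the values (cued or uncued path).
#' @param cue cue environment id (must be on `path`).
#' @return named numeric vector over offsets "-4".."4".
#' @export
trial_profile <- function(cue_pattern, templates, path, cue) {
  d_set <- distinct_offsets()
  envs <- neighbor(path, cue, d_set)
  vals <- vapply(seq_along(d_set), function(i) {
    corr_or_stop(cue_pattern, templates[envs[i] + 1L, ],
                 paste0("environment ", envs[i]))
  }, numeric(1))
  out <- c(vals[d_set == 4L], vals)   # duplicate the +4 value at -4
  names(out) <- as.character(profile_offsets())
  out
}

#' Participant-level mean profile
#'
#' Position-wise mean of trial-type profiles (all cues, both maps, both path
#' colors) for one participant.
#'
#' @param trial_profiles matrix with one row per trial-type profile (columns
#'   "-4".."4"), or a list of profile vectors.
#' @param participant optional participant ids per profile; must be constant.
#' @return named numeric vector over offsets "-4".."4".
#' @export
participant_profile <- function(trial_profiles, participant = NULL) {
  if (is.list(trial_profiles)) trial_profiles <- do.call(rbind, trial_profiles)
  if (!is.null(participant) && length(unique(participant)) > 1)
    stop("profiles from multiple participants cannot be averaged")
  stopifnot(nrow(trial_profiles) >= 1)
  colMeans(trial_profiles)
}

#' Different-map baseline
#'
#' Correlates each cue-period pattern with the voxel-wise mean of the other
#' map's eight templates, then averages over trial types; one scalar per
#' participant.
#'
#' @param cue_patterns matrix `trial type x voxel`.
#' @param other_map_templates matrix `8 x voxel` of the other map's templates.
#' @return scalar baseline correlation.
#' @export
different_map_baseline <- function(cue_patterns, other_map_templates) {
  stopifnot(nrow(other_map_templates) == 8)
  ref <- colMeans(other_map_templates)
  vals <- vapply(seq_len(nrow(cue_patterns)), function(t) {
    corr_or_stop(cue_patterns[t, ], ref, "different-map mean template")
  }, numeric(1))
  mean(vals)
}

#' Cue-centered profiles for every participant of a study
#'
#' Runs the full similarity stage: for each participant, held-out templates
#' are built from the other participants' localizer betas on the ROI, each of
#' the 32 trial-type patterns is correlated with the 16 templates, the eight
#' same-map values are arranged by the cued (or uncued) path's order, and
#' trial-type profiles are averaged into one 9-point profile per participant.
#' The different-map baseline is computed alongside.
#'
#' @param study a [synthetic_study()] (or any object with the same fields).
#' @param roi voxel indices; defaults to all voxels.
#' @param ordering `"cued"` arranges values by the cued path,
#'   `"uncued"` arranges the same correlations by the other path's order.
#' @return list with `profiles` (matrix `participant x 9`, columns "-4".."4")
#'   and `baseline` (numeric per participant).
#' @export
study_profiles <- function(study, roi = NULL, ordering = c("cued", "uncued")) {
  ordering <- match.arg(ordering)
  roi <- roi %||% seq_len(dim(study$localizer)[3])
  n <- dim(study$localizer)[1]
  tt <- study$trial_types
  d_set <- distinct_offsets()
  map_envs <- list(A = 0:7, B = 8:15)
  profiles <- matrix(NA_real_, n, 9,
                     dimnames = list(NULL, as.character(profile_offsets())))
  baseline <- numeric(n)
  for (p in seq_len(n)) {
    tmpl <- heldout_templates(study$localizer, roi, p)
    pat <- study$anticipation[p, , roi, drop = TRUE]
    cmat <- cor(t(pat), t(tmpl))              # trial x 16 env correlations
    acc <- matrix(0, nrow(tt), 9)
    base_vals <- numeric(nrow(tt))
    for (t in seq_len(nrow(tt))) {
      m <- tt$map[t]
      color <- if (ordering == "cued") tt$path[t]
               else setdiff(c("green", "blue"), tt$path[t])
      path <- study$designs[[m]][[color]]
      envs <- neighbor(path, tt$cue[t], d_set)
      vals <- cmat[t, envs + 1L]
      acc[t, ] <- c(vals[d_set == 4L], vals)
      other <- setdiff(c("A", "B"), m)
      base_vals[t] <- cor(pat[t, ], colMeans(tmpl[map_envs[[other]] + 1L, ]))
    }
    profiles[p, ] <- colMeans(acc)
    baseline[p] <- mean(base_vals)
  }
  list(profiles = profiles, baseline = baseline, ordering = ordering)
}

#' Export participant profiles as a tidy TSV
#'
#' @param prof result of [study_profiles()].
#' @param path output file.
#' @export
write_profiles_tsv <- function(prof, path) {
  n <- nrow(prof$profiles)
  long <- do.call(rbind, lapply(seq_len(n), function(p) {
    data.frame(participant = p, ordering = prof$ordering,
               d = profile_offsets(), value = unname(prof$profiles[p, ]),
               baseline = prof$baseline[p])
  }))
  write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
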