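# build the fitted point matrix from a profile matrix: drop the duplicated
# -4 column for the distinct-value view, or the cue column when excluded
profile_points <- function(profiles, include_cue = TRUE) {
  d <- as.numeric(colnames(profiles))
  keep <- if (include_cue) rep(TRUE, length(d)) else d != 0
  list(P = profiles[, keep, drop = FALSE], d = d[keep])
}

profile_distinct <- function(profiles, include_cue = TRUE) {
  d <- as.numeric(colnames(profiles))
  keep <- d >= -3
  if (!include_cue) keep <- keep & d != 0
  list(V = profiles[, keep, drop = FALSE], d = d[keep])
}

#' Leave-one-participant-out group fit error
#'
#' For each held-out participant, fits the asymmetric Gaussian to the
#' position-wise mean profile of the remaining participants and scores the
#' sum of squared errors when predicting the held-out profile; returns the
#' mean over all choices of held-out participant.
#'
#' @param profiles matrix `participant x offsets` ("-4".."4").
#' @param include_cue drop the d = 0 point from fitting and scoring if FALSE.
#' @param penalty_strength,width_max fitting controls, see [fit_profile()].
#' @return mean leave-one-out SSE (scalar).
#' @export
loo_group_error <- function(profiles, include_cue = TRUE,
                            penalty_strength = 0.01, width_max = 10) {
  if (nrow(profiles) < 2) stop("need at least 2 participants")
  pts <- profile_points(profiles, include_cue)
  cpp_loo_error(pts$P, pts$d, penalty_strength, width_max)
}

#' Shuffled-order null distribution of the group fit error
#'
#' Each shuffle permutes, independently for every participant, the distinct
#' similarity values across the distinct circular positions (8 values
#' including the cue, 7 excluding it), rebuilds the profile with the
#' four-step value duplicated at both ends, and recomputes the leave-one-out
#' group error.
#'
#' @inheritParams loo_group_error
#' @param n_shuffles number of shuffles (10000 for faithful runs; smaller for
#'   simulation studies).
#' @param seed optional seed; the null is deterministic given it.
#' @return object of class `"null_distribution"`: list with `errors`,
#'   `n_shuffles`, `include_cue`, `seed`.
#' @export
shuffled_null <- function(profiles, include_cue = TRUE, n_shuffles = 10000,
                          seed = NULL, penalty_strength = 0.01,
                          width_max = 10) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (nrow(profiles) < 2) stop("need at least 2 participants")
  if (!is.null(seed)) set.seed(seed)
  dv <- profile_distinct(profiles, include_cue)
  errors <- cpp_shuffled_null(dv$V, dv$d, TRUE, penalty_strength, width_max,
                              as.integer(n_shuffles))
  structure(list(errors = errors, n_shuffles = as.integer(n_shuffles),
                 include_cue = include_cue, seed = seed),
            class = "null_distribution")
}

#' Permutation p-value and R-squared
#'
#' `p` is the fraction of shuffles whose group error is strictly below the
#' observed error; `r_squared` is one minus the observed error divided by the
#' mean null error, so it is positive exactly when the correctly ordered data
#' fit better than the average shuffle.
#'
#' @param observed_error observed leave-one-out group error.
#' @param null a [shuffled_null()] result (or numeric vector of null errors).
#' @param smooth use the (1 + k) / (1 + n) smoothed p-value (for small
#'   shuffle counts).
#' @return list with `observed_error`, `p`, `r_squared`, `n_shuffles`.
#' @export
permutation_result <- function(observed_error, null, smooth = FALSE) {
  errors <- if (inherits(null, "null_distribution")) null$errors else null
  if (length(errors) == 0) stop("null distribution is empty")
  mnull <- mean(errors)
  if (mnull == 0) stop("mean null error is zero; R-squared undefined")
  k <- sum(errors < observed_error)
  p <- if (smooth) (1 + k) / (1 + length(errors)) else k / length(errors)
  list(observed_error = observed_error, p = p,
       r_squared = 1 - observed_error / mnull, n_shuffles = length(errors))
}

#' Cued- versus uncued-path contrast
#'
#' Tests whether the Gaussian fit (cue excluded) is better for similarity
#' values arranged by the cued path than by the uncued path. The observed
#' statistic is `error(uncued) - error(cued)`; the null pairs, per shuffle,
#' a shuffled-order error for each arrangement, and `p` is the fraction of
#' null differences at least as large as the observed one.
#'
#' @param cued,uncued profile matrices from the same participants.
#' @param n_shuffles,seed,penalty_strength,width_max as in [shuffled_null()].
#' @return list with `delta_obs`, `p`, `error_cued`, `error_uncued`.
#' @export
cued_vs_uncued_test <- function(cued, uncued, n_shuffles = 10000, seed = NULL,
                                penalty_strength = 0.01, width_max = 10) {
  if (nrow(cued) != nrow(uncued))
    stop("cued and uncued profiles must come from the same participants")
  err_c <- loo_group_error(cued, include_cue = FALSE,
                           penalty_strength = penalty_strength,
                           width_max = width_max)
  err_u <- loo_group_error(uncued, include_cue = FALSE,
                           penalty_strength = penalty_strength,
                           width_max = width_max)
  delta_obs <- err_u - err_c
  if (!is.null(seed)) set.seed(seed)
  dv_c <- profile_distinct(cued, include_cue = FALSE)
  dv_u <- profile_distinct(uncued, include_cue = FALSE)
  null_c <- cpp_shuffled_null(dv_c$V, dv_c$d, TRUE, penalty_strength,
                              width_max, as.integer(n_shuffles))
  null_u <- cpp_shuffled_null(dv_u$V, dv_u$d, TRUE, penalty_strength,
                              width_max, as.integer(n_shuffles))
  p <- mean((null_u - null_c) >= delta_obs)
  list(delta_obs = delta_obs, p = p,
       error_cued = err_c, error_uncued = err_u, n_shuffles = n_shuffles)
}

#' Group tests on the fitted Gaussian parameters
#'
#' One-sample t-tests of amplitude above and asymptote below the
#' different-map baseline (two-tailed), and a Wilcoxon signed-rank test of
#' forward versus backward widths. Parameter tests are meant to be read only
#' when the permutation test of the Gaussian fit is itself significant; pass
#' `permutation_p` to have that gate recorded.
#'
#' @param fits per-participant fit table from [fit_participants()].
#' @param baselines per-participant different-map baseline.
#' @param amplitude_measure compare `A` (default) or the peak `A + b` to the
#'   baseline.
#' @param permutation_p optional p-value of the permutation test used as gate.
#' @param alpha gate level (default 0.05).
#' @return list of class `"param_group_stats"` with `amplitude`, `asymptote`
#'   (each: mean, sd, t, df, p), `widths` (V, p), `n`, and `gated`.
#' @export
parameter_group_tests <- function(fits, baselines,
                                  amplitude_measure = c("A", "peak"),
                                  permutation_p = NULL, alpha = 0.05) {
  amplitude_measure <- match.arg(amplitude_measure)
  n <- nrow(fits)
  if (n < 3) stop("need at least 3 participants")
  stopifnot(length(baselines) == n)
  amp <- if (amplitude_measure == "A") fits$A else fits$A + fits$b
  one_sample <- function(x, label) {
    if (sd(x) == 0)
      stop("zero variance of ", label, " differences; t-test undefined")
    tt <- t.test(x)
    list(mean = mean(x), sd = sd(x), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
  }
  d_amp <- amp - baselines
  d_asy <- fits$b - baselines
  wdiff <- fits$sigma_f - fits$sigma_b
  widths <- if (all(wdiff == 0)) {
    list(V = 0, p = 1, note = "all width differences zero")
  } else {
    wt <- suppressWarnings(wilcox.test(fits$sigma_f, fits$sigma_b,
                                       paired = TRUE))
    list(V = unname(wt$statistic), p = wt$p.value)
  }
  gated <- if (is.null(permutation_p)) NA else permutation_p < alpha
  if (isFALSE(gated))
    warning("permutation test not significant; parameter tests are not ",
            "interpretable under the analysis's gating rule")
  structure(list(amplitude = one_sample(d_amp, "amplitude-baseline"),
                 asymptote = one_sample(d_asy, "asymptote-baseline"),
                 widths = widths, n = n, gated = gated,
                 amplitude_measure = amplitude_measure),
            class = "param_group_stats")
}
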