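#' Ground-truth similarity profile for the synthetic generator
#'
#' The generator plants a cue-centered mixing profile
#' `w(d) = b + A * exp(-d^2 / (2 * sigma(d)^2))` with `sigma(d) = sigma_b` for
#' past steps (d < 0) and `sigma_f` for the cue and future steps, mirroring
#' the asymmetric Gaussian the analysis fits.
#'
#' @param A peak mixing weight above the asymptote.
#' @param b asymptote mixing weight shared by all environments.
#' @param sigma_f,sigma_b forward and backward widths, in steps (> 0).
#' @return list of class `"ground_truth_profile"`.
#' @export
ground_truth_profile <- function(A = 1, b = 0.05, sigma_f = 1.5, sigma_b = 2.5) {
  stopifnot(sigma_f > 0, sigma_b > 0, is.finite(A), is.finite(b))
  structure(list(A = A, b = b, sigma_f = sigma_f, sigma_b = sigma_b),
            class = "ground_truth_profile")
}

#' @rdname ground_truth_profile
#' @param profile a ground-truth profile.
#' @param d step offsets (vectorized).
#' @export
profile_weights <- function(profile, d = distinct_offsets()) {
  asym_gauss(d, profile$A, profile$b, profile$sigma_f, profile$sigma_b)
}

#' Configuration of a synthetic study
#'
#' Defaults describe the emulated study: 32 participants, 16 environments in
#' two maps of 8, 32 trial types (16 cues x 2 paths), and a planted
#' asymmetric profile with a wider backward than forward width.
#'
#' @param n_participants number of participants (>= 2).
#' @param n_voxels voxels per region (>= 2).
#' @param localizer_noise_sd per-voxel Gaussian noise sd on localizer betas.
#' @param anticipation_noise_sd noise sd on anticipation-period patterns.
#' @param profile planted [ground_truth_profile()].
#' @param b_participant_sd across-participant sd of the planted asymptote
#'   weight (0 = identical profiles for everyone).
#' @param behavior list of behavioral generator settings: `slope_ms_per_step`,
#'   `intercept_ms`, `noise_sd_ms`, `p_correct`, `n_trials`, and
#'   `coupling_ms` (ms of extra RT slope per unit *decrease* of a
#'   participant's planted asymptote weight; 0 = uncoupled).
#' @param seed integer seed; every generator draw derives from it.
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_participants = 32, n_voxels = 2000,
                             localizer_noise_sd = 0.5,
                             anticipation_noise_sd = 0.5,
                             profile = ground_truth_profile(),
                             b_participant_sd = 0,
                             behavior = list(),
                             seed = 1) {
  stopifnot(n_participants >= 2, n_voxels >= 2,
            localizer_noise_sd >= 0, anticipation_noise_sd >= 0,
            b_participant_sd >= 0)
  beh <- utils::modifyList(
    list(slope_ms_per_step = 126, intercept_ms = 1000, noise_sd_ms = 150,
         p_correct = 0.8686, n_trials = 64, coupling_ms = 0),
    behavior)
  structure(list(n_participants = as.integer(n_participants),
                 n_voxels = as.integer(n_voxels),
                 localizer_noise_sd = localizer_noise_sd,
                 anticipation_noise_sd = anticipation_noise_sd,
                 profile = profile,
                 b_participant_sd = b_participant_sd,
                 behavior = beh,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Ground-truth environment tuning matrix
#'
#' Independent per-environment voxel tuning rows, standardized to zero mean
#' and unit variance per row; stands in for the true environment-evoked
#' activity patterns.
#'
#' @param n_envs number of environments (16).
#' @param n_voxels number of voxels (>= 2).
#' @param seed optional seed.
#' @return `n_envs x n_voxels` matrix.
#' @export
make_templates <- function(n_envs = 16, n_voxels = 2000, seed = NULL) {
  if (n_voxels < 2) stop("n_voxels must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n_envs * n_voxels), n_envs, n_voxels)
  m <- (m - rowMeans(m)) / apply(m, 1, sd)
  m
}

#' Simulate localizer betas
#'
#' Each participant's beta vector for an environment is the ground-truth
#' tuning row plus isotropic Gaussian noise, so across-participant
#' reliability falls monotonically with the noise sd.
#'
#' @param truth tuning matrix from [make_templates()].
#' @param config a [synthetic_config()].
#' @return array `participant x environment x voxel`.
#' @export
simulate_localizer <- function(truth, config) {
  n <- config$n_participants
  ne <- nrow(truth)
  nv <- ncol(truth)
  out <- array(NA_real_, c(n, ne, nv))
  for (p in seq_len(n)) {
    out[p, , ] <- truth +
      matrix(rnorm(ne * nv, sd = config$localizer_noise_sd), ne, nv)
  }
  out
}

# the 32 trial types: each environment cued once per path color on its map
trial_type_table <- function() {
  rbind(
    expand.grid(map = "A", path = c("green", "blue"), cue = 0:7,
                stringsAsFactors = FALSE),
    expand.grid(map = "B", path = c("green", "blue"), cue = 8:15,
                stringsAsFactors = FALSE))
}

#' Simulate anticipation-period patterns
#'
#' The cue-period pattern for a trial type (cue, path) is a graded mixture of
#' the surrounding environments' tuning rows along the *cued* path's order,
#' weighted by the planted profile, plus noise. The weight at |d| = 4 is
#' applied once (the forward and backward four-step neighbors are the same
#' environment). No structure is planted along the uncued path's order.
#'
#' @param truth tuning matrix (16 x voxel).
#' @param designs list with map designs `A` and `B`.
#' @param config a [synthetic_config()].
#' @param b_by_participant optional per-participant asymptote weights
#'   (defaults to the shared planted value).
#' @return list with `patterns` (array `participant x trial type x voxel`)
#'   and `trial_types` (data frame map/path/cue).
#' @export
simulate_anticipation <- function(truth, designs, config,
                                  b_by_participant = NULL) {
  for (m in c("A", "B"))
    if (!isTRUE(c(check_path_constraint(designs[[m]]))))
      stop("design for map ", m, " violates the path constraint")
  tt <- trial_type_table()
  n <- config$n_participants
  nv <- ncol(truth)
  pf <- config$profile
  bs <- b_by_participant %||% rep(pf$b, n)
  stopifnot(length(bs) == n)
  d_set <- distinct_offsets()  # -3..4: one weight per distinct environment
  out <- array(NA_real_, c(n, nrow(tt), nv))
  for (p in seq_len(n)) {
    w <- asym_gauss(d_set, pf$A, bs[p], pf$sigma_f, pf$sigma_b)
    for (t in seq_len(nrow(tt))) {
      path <- designs[[tt$map[t]]][[tt$path[t]]]
      envs <- neighbor(path, tt$cue[t], d_set)
      sig <- drop(w %*% truth[envs + 1L, , drop = FALSE])
      out[p, t, ] <- sig + rnorm(nv, sd = config$anticipation_noise_sd)
    }
  }
  list(patterns = out, trial_types = tt)
}

#' Simulate anticipation-task behavior
#'
#' Trials are balanced across steps-into-the-future 1..4; response time is
#' linear in steps with Gaussian noise (truncated at zero), and accuracy is
#' Bernoulli.
#'
#' @param n_participants number of participants.
#' @param slope_ms_per_step RT cost per step, ms; scalar or one value per
#'   participant.
#' @param intercept_ms RT intercept, ms.
#' @param p_correct probability of a correct response.
#' @param seed optional seed.
#' @param n_trials trials per participant (multiple of 4).
#' @param noise_sd_ms RT noise sd, ms.
#' @return data frame of trial records: `participant`, `map`, `path`, `cue`,
#'   `steps`, `correct`, `rt` (seconds).
#' @export
simulate_behavior <- function(n_participants, slope_ms_per_step = 126,
                              intercept_ms = 1000, p_correct = 0.8686,
                              seed = NULL, n_trials = 64, noise_sd_ms = 150) {
  stopifnot(is.finite(intercept_ms), all(is.finite(slope_ms_per_step)),
            p_correct > 0, p_correct <= 1, n_trials %% 4 == 0)
  if (!is.null(seed)) set.seed(seed)
  slopes <- rep_len(slope_ms_per_step, n_participants)
  tt <- trial_type_table()
  rows <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    type_idx <- rep_len(seq_len(nrow(tt)), n_trials)
    steps <- sample(rep(1:4, n_trials / 4))
    rt_ms <- intercept_ms + slopes[p] * steps + rnorm(n_trials, sd = noise_sd_ms)
    rows[[p]] <- data.frame(
      participant = p,
      map = tt$map[type_idx], path = tt$path[type_idx], cue = tt$cue[type_idx],
      steps = steps,
      correct = runif(n_trials) < p_correct,
      rt = pmax(rt_ms, 1) / 1000)
  }
  do.call(rbind, rows)
}

#' Generate a complete synthetic study
#'
#' Draws the map designs (the green-to-blue reindexing is shared across
#' maps), the ground-truth tuning, localizer and anticipation patterns, and
#' the behavioral table, all from `config$seed`. When
#' `config$behavior$coupling_ms` is nonzero, a participant's RT slope is
#' `slope_ms_per_step - coupling_ms * (b_p - mean(b_p))`, planting the
#' lower-asymptote-steeper-slope linkage.
#'
#' @param config a [synthetic_config()].
#' @return list of class `"seqgauss_study"`.
#' @export
synthetic_study <- function(config = synthetic_config()) {
  set.seed(config$seed)
  reindex <- sample_valid_reindex()
  designs <- list(
    A = generate_map_design(0:7, reindex = reindex, map = "A"),
    B = generate_map_design(8:15, reindex = reindex, map = "B"))
  truth <- make_templates(16, config$n_voxels)
  localizer <- simulate_localizer(truth, config)
  b_p <- config$profile$b +
    rnorm(config$n_participants, sd = config$b_participant_sd)
  ant <- simulate_anticipation(truth, designs, config, b_by_participant = b_p)
  beh <- config$behavior
  slopes <- beh$slope_ms_per_step - beh$coupling_ms * (b_p - mean(b_p))
  behavior <- simulate_behavior(
    config$n_participants, slope_ms_per_step = slopes,
    intercept_ms = beh$intercept_ms, p_correct = beh$p_correct,
    n_trials = beh$n_trials, noise_sd_ms = beh$noise_sd_ms)
  structure(list(config = config, designs = designs, truth = truth,
                 localizer = localizer, anticipation = ant$patterns,
                 trial_types = ant$trial_types, behavior = behavior,
                 b_by_participant = b_p),
            class = "seqgauss_study")
}
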