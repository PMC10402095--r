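# voxel indices of the cube anchored at (ax, ay, az), in grid linear order
cube_voxels <- function(anchor, side, dims) {
  xs <- anchor[1]:(anchor[1] + side - 1)
  ys <- anchor[2]:(anchor[2] + side - 1)
  zs <- anchor[3]:(anchor[3] + side - 1)
  idx <- outer(xs, (ys - 1) * dims[1], `+`)
  idx <- outer(c(idx), (zs - 1) * dims[1] * dims[2], `+`)
  c(idx)
}

# anchors of the cube lattice: start at the grid origin, step fixed, cubes
# extending past the edge are dropped
cube_anchors <- function(dims, side, step) {
  axes <- lapply(dims, function(n) {
    if (n < side) integer(0) else seq(1L, n - side + 1L, by = step)
  })
  as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]]))
}

#' Cube searchlight over a voxel grid
#'
#' Moves a cube of `side` voxels across the grid in steps of `step`. In each
#' cube with at least `min_reliable` environment-reliable voxels, the full
#' similarity-and-fit stage runs per participant: held-out templates on the
#' cube's reliable voxels, 32 trial-type correlations arranged by the cued
#' path, the participant-mean profile, the asymmetric Gaussian fit, and a
#' goodness of fit `g = 1 - sse_correct / mean(sse_shuffled)` from
#' `n_shuffles` order shuffles of that participant's profile. Cube results
#' are assigned to every voxel in the cube and finalized by unweighted
#' averaging over all cubes containing the voxel.
#'
#' @param volume a [simulate_volume()] dataset (or compatible object).
#' @param side cube side length in voxels (default 7).
#' @param step lattice step in voxels (default 2).
#' @param min_reliable minimum environment-reliable voxels per cube
#'   (default 64).
#' @param n_shuffles order shuffles per participant per cube for the
#'   goodness map (default 100).
#' @param seed optional seed for the shuffles.
#' @param penalty_strength,width_max fitting controls.
#' @return object of class `"parameter_maps"`: matrices
#'   `participant x voxel` for `A`, `b`, `sigma_f`, `sigma_b`, `g` (NA where
#'   uncovered), plus `coverage`, `y`, `dims`, `n_cubes_run`.
#' @export
run_searchlight <- function(volume, side = 7, step = 2, min_reliable = 64,
                            n_shuffles = 100, seed = NULL,
                            penalty_strength = 0.01, width_max = 10) {
  dims <- volume$dims
  if (any(dims < side)) stop("grid smaller than the searchlight cube")
  if (!is.null(seed)) set.seed(seed)
  anchors <- cube_anchors(dims, side, step)
  n <- dim(volume$localizer)[1]
  nvox <- prod(dims)
  acc <- lapply(c("A", "b", "sigma_f", "sigma_b", "g"),
                function(nm) matrix(0, n, nvox))
  names(acc) <- c("A", "b", "sigma_f", "sigma_b", "g")
  coverage <- integer(nvox)
  d_dist <- distinct_offsets()
  n_run <- 0L
  for (ci in seq_len(nrow(anchors))) {
    vox <- cube_voxels(anchors[ci, ], side, dims)
    vox <- vox[volume$reliable_mask[vox]]
    if (length(vox) < min_reliable) next
    n_run <- n_run + 1L
    prof <- study_profiles(volume, roi = vox, ordering = "cued")
    for (p in seq_len(n)) {
      f <- fit_profile(prof$profiles[p, ],
                       penalty_strength = penalty_strength,
                       width_max = width_max)
      dvals <- prof$profiles[p, as.character(d_dist)]
      sse_null <- cpp_shuffled_fit_sse(as.numeric(dvals), d_dist, TRUE,
                                       penalty_strength, width_max,
                                       as.integer(n_shuffles))
      g <- 1 - f$sse / mean(sse_null)
      acc$A[p, vox] <- acc$A[p, vox] + f$A
      acc$b[p, vox] <- acc$b[p, vox] + f$b
      acc$sigma_f[p, vox] <- acc$sigma_f[p, vox] + f$sigma_f
      acc$sigma_b[p, vox] <- acc$sigma_b[p, vox] + f$sigma_b
      acc$g[p, vox] <- acc$g[p, vox] + g
    }
    coverage[vox] <- coverage[vox] + 1L
  }
  if (n_run == 0L) warning("no cube reached the minimum reliable-voxel count")
  for (nm in names(acc)) {
    acc[[nm]] <- sweep(acc[[nm]], 2, pmax(coverage, 1L), `/`)
    acc[[nm]][, coverage == 0L] <- NA_real_
  }
  structure(c(acc, list(coverage = coverage, y = volume$y, dims = dims,
                        n_cubes_run = n_run)),
            class = "parameter_maps")
}

#' Voxelwise group test of the goodness map
#'
#' One-sample, one-sided t-test per covered voxel of the per-participant
#' goodness values against zero, with optional Benjamini-Hochberg correction
#' across voxels.
#'
#' @param maps a [run_searchlight()] result.
#' @param fdr apply Benjamini-Hochberg across tested voxels.
#' @return data frame with `voxel`, `t`, `p`, and `p_fdr`; voxels with zero
#'   variance are flagged NA.
#' @export
voxelwise_group_test <- function(maps, fdr = TRUE) {
  g <- maps$g
  tested <- which(maps$coverage >= 1)
  n <- nrow(g)
  if (n < 3) stop("need at least 3 participants")
  mu <- colMeans(g[, tested, drop = FALSE])
  s <- apply(g[, tested, drop = FALSE], 2, sd)
  tstat <- ifelse(s > 0, mu / (s / sqrt(n)), NA_real_)
  p <- pt(tstat, df = n - 1, lower.tail = FALSE)
  out <- data.frame(voxel = tested, t = tstat, p = p)
  out$p_fdr <- if (fdr) p.adjust(p, method = "BH") else NA_real_
  out
}

# Spearman correlation of x with y; optionally partial, removing the ranks of
# a control variable from both via linear regression on ranks
spearman_rho <- function(x, y, control = NULL) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  if (is.null(control)) return(cor(rx, ry))
  rz <- rank(control)
  ex <- stats::resid(lm(rx ~ rz))
  ey <- stats::resid(lm(ry ~ rz))
  if (sd(ex) == 0 || sd(ey) == 0) return(NA_real_)
  cor(ex, ey)
}

# group-level one-sample t of per-participant correlations; identical
# correlations (e.g. a perfect planted gradient) make the statistic 0/0, so
# a nonzero constant is reported as overwhelming evidence rather than error
group_rho_test <- function(rho_ok) {
  if (sd(rho_ok) == 0) {
    if (mean(rho_ok) == 0) stop("all correlations are exactly zero")
    return(list(t = sign(mean(rho_ok)) * Inf, df = length(rho_ok) - 1, p = 0))
  }
  tt <- t.test(rho_ok)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

map_target <- function(maps, target) {
  switch(target,
         width = (maps$sigma_f + maps$sigma_b) / 2,
         A = maps$A, b = maps$b, g = maps$g,
         sigma_f = maps$sigma_f, sigma_b = maps$sigma_b,
         stop("unknown target ", target))
}

#' Posterior-anterior gradient of a fitted parameter within a region
#'
#' Per participant, the Spearman rank correlation across the region's voxels
#' between a fitted parameter (by default the mean of the forward and
#' backward widths) and the voxel y-coordinate; significance at the group
#' level by a two-sided one-sample t-test of the per-participant
#' correlations against zero. A partial variant controls for another
#' parameter (e.g. amplitude) on ranks.
#'
#' @param maps a [run_searchlight()] result.
#' @param region voxel indices of the region.
#' @param target one of `"width"`, `"A"`, `"b"`, `"g"`, `"sigma_f"`,
#'   `"sigma_b"`.
#' @param control optional target name to partial out.
#' @return list with `rho` (per participant), `mean_rho`, `t`, `df`, `p`,
#'   `n_excluded`.
#' @export
within_region_gradient <- function(maps, region, target = "width",
                                   control = NULL) {
  region <- intersect(region, which(maps$coverage >= 1))
  if (length(region) < 3) stop("need at least 3 covered voxels in the region")
  tv <- map_target(maps, target)[, region, drop = FALSE]
  cv <- if (is.null(control)) NULL
        else map_target(maps, control)[, region, drop = FALSE]
  yv <- maps$y[region]
  rho <- vapply(seq_len(nrow(tv)), function(p) {
    spearman_rho(tv[p, ], yv, control = if (is.null(cv)) NULL else cv[p, ])
  }, numeric(1))
  n_excl <- sum(is.na(rho))
  if (n_excl > 0)
    warning(n_excl, " participant(s) with undefined correlation excluded")
  rho_ok <- rho[!is.na(rho)]
  if (length(rho_ok) < 3) stop("fewer than 3 defined correlations")
  tt <- group_rho_test(rho_ok)
  list(rho = rho, mean_rho = mean(rho_ok), t = tt$t,
       df = tt$df, p = tt$p, n_excluded = n_excl)
}

#' Hierarchy of a fitted parameter across ordered regions
#'
#' Averages the target parameter across each region's voxels per participant
#' and correlates (Spearman) the region means with the region's rank in the
#' supplied order; group-level significance by one-sample t-test.
#'
#' @param maps a [run_searchlight()] result.
#' @param regions named list of voxel-index vectors, ordered along the
#'   hierarchy (rank 1 first).
#' @param target parameter name, as in [within_region_gradient()].
#' @return list with `rho`, `mean_rho`, `t`, `df`, `p`, `region_means`.
#' @export
across_region_hierarchy <- function(maps, regions, target = "width") {
  if (length(regions) < 3) stop("need at least 3 regions")
  for (nm in names(regions)) {
    reg <- intersect(regions[[nm]], which(maps$coverage >= 1))
    if (length(reg) == 0) stop("region ", nm, " has no covered voxels")
    regions[[nm]] <- reg
  }
  tv <- map_target(maps, target)
  n <- nrow(tv)
  means <- sapply(regions, function(reg)
    rowMeans(tv[, reg, drop = FALSE]))          # participant x region
  ranks <- seq_along(regions)
  rho <- vapply(seq_len(n), function(p) spearman_rho(means[p, ], ranks),
                numeric(1))
  rho_ok <- rho[!is.na(rho)]
  if (length(rho_ok) < 3) stop("fewer than 3 defined correlations")
  tt <- group_rho_test(rho_ok)
  list(rho = rho, mean_rho = mean(rho_ok), t = tt$t,
       df = tt$df, p = tt$p, region_means = means)
}
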