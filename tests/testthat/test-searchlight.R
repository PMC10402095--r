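small_volume <- function(seed = 61, dims = c(9, 9, 9), wg = 0, ag = 0,
                         n_part = 4, noise = 0.2) {
  simulate_volume(
    grid_dims = dims, width_gradient = wg, amplitude_gradient = ag,
    config = synthetic_config(n_participants = n_part, n_voxels = 2,
                              anticipation_noise_sd = noise,
                              localizer_noise_sd = 0.3, seed = seed))
}

test_that("cube lattice anchors and membership match their definitions", {
  a <- seqgauss:::cube_anchors(c(12, 12, 12), side = 7, step = 2)
  expect_equal(sort(unique(a[, 1])), c(1, 3, 5))
  expect_equal(nrow(a), 27)
  # grid smaller than the cube yields no anchors
  expect_equal(nrow(seqgauss:::cube_anchors(c(6, 12, 12), 7, 2)), 0)
  vox <- seqgauss:::cube_voxels(c(1, 1, 1), 2, c(4, 4, 4))
  expect_setequal(vox, c(1, 2, 5, 6, 17, 18, 21, 22))
})

test_that("overlap averaging equals a brute-force membership oracle", {
  vol <- small_volume(seed = 62, dims = c(9, 9, 9))
  maps <- run_searchlight(vol, side = 7, step = 2, min_reliable = 30,
                          n_shuffles = 5, seed = 1)
  # oracle: recompute each cube's fits directly, list every voxel's cube
  # memberships by coordinate arithmetic, and average in the same cube order
  anchors <- expand.grid(x = c(1, 3), y = c(1, 3), z = c(1, 3))
  cube_fits <- list()
  cube_members <- list()
  for (ci in seq_len(nrow(anchors))) {
    a <- as.numeric(anchors[ci, ])
    inside <- vol$coords[, 1] >= a[1] & vol$coords[, 1] <= a[1] + 6 &
      vol$coords[, 2] >= a[2] & vol$coords[, 2] <= a[2] + 6 &
      vol$coords[, 3] >= a[3] & vol$coords[, 3] <= a[3] + 6
    vox <- which(inside & vol$reliable_mask)
    if (length(vox) < 30) next
    prof <- study_profiles(vol, roi = vox)
    fits <- fit_participants(prof$profiles)
    cube_fits[[length(cube_fits) + 1]] <- fits
    cube_members[[length(cube_members) + 1]] <- vox
  }
  expect_equal(maps$n_cubes_run, length(cube_fits))
  nvox <- prod(vol$dims)
  for (v in seq_len(nvox)) {
    in_cubes <- which(vapply(cube_members, function(m) v %in% m, logical(1)))
    expect_equal(maps$coverage[v], length(in_cubes))
    if (length(in_cubes) == 0) {
      expect_true(all(is.na(maps$sigma_f[, v])))
      next
    }
    for (p in 1:4) {
      sf <- mean(vapply(in_cubes, function(ci) cube_fits[[ci]]$sigma_f[p],
                        numeric(1)))
      A <- mean(vapply(in_cubes, function(ci) cube_fits[[ci]]$A[p],
                       numeric(1)))
      expect_equal(maps$sigma_f[p, v], sf, tolerance = 1e-12)
      expect_equal(maps$A[p, v], A, tolerance = 1e-12)
    }
  }
})

test_that("searchlight maps are deterministic given the seed", {
  vol <- small_volume(seed = 63, dims = c(7, 9, 7))
  m1 <- run_searchlight(vol, min_reliable = 20, n_shuffles = 10, seed = 5)
  m2 <- run_searchlight(vol, min_reliable = 20, n_shuffles = 10, seed = 5)
  expect_identical(m1$g, m2$g)
  expect_identical(m1$sigma_f, m2$sigma_f)
})

test_that("a homogeneous volume yields identical parameters at every voxel", {
  vol <- small_volume(seed = 64, dims = c(7, 7, 7), noise = 0)
  vol$reliable_mask[] <- TRUE
  maps <- run_searchlight(vol, min_reliable = 20, n_shuffles = 5, seed = 2)
  # a 7^3 grid holds exactly one cube; every voxel inherits its values
  expect_equal(maps$n_cubes_run, 1)
  expect_equal(length(unique(round(maps$sigma_f[1, ], 10))), 1)
})

test_that("voxelwise group test flags degenerate voxels and detects signal", {
  vol <- small_volume(seed = 65, dims = c(7, 7, 7))
  maps <- run_searchlight(vol, min_reliable = 10, n_shuffles = 10, seed = 3)
  # g identically zero -> no rejections
  maps0 <- maps
  maps0$g[] <- 0
  r0 <- voxelwise_group_test(maps0)
  expect_true(all(is.na(r0$t)))
  # analytic check: g ~ N(0.5, 0.1^2) over 32 participants at one voxel
  maps1 <- maps
  set.seed(66)
  maps1$g <- matrix(rnorm(32 * ncol(maps$g), 0.5, 0.1), 32)
  maps1$coverage <- rep(1L, ncol(maps$g))
  r1 <- voxelwise_group_test(maps1)
  expect_true(all(r1$p < 1e-6))
})

test_that("a planted width gradient is recovered, also when controlling amplitude", {
  vol <- simulate_volume(
    grid_dims = c(7, 15, 7), width_gradient = 0.08, amplitude_gradient = 0,
    config = synthetic_config(n_participants = 8, n_voxels = 2,
                              anticipation_noise_sd = 6,
                              localizer_noise_sd = 0.3, seed = 67))
  maps <- run_searchlight(vol, min_reliable = 30, n_shuffles = 5, seed = 4)
  region <- which(maps$coverage >= 1)
  gw <- within_region_gradient(maps, region, target = "width")
  gp <- within_region_gradient(maps, region, target = "width", control = "A")
  expect_lt(gw$p, 0.05)
  expect_gt(gw$mean_rho, 0)
  # the gradient survives controlling for amplitude (it is not an
  # amplitude artifact)
  expect_lt(gp$p, 0.05)
  expect_gt(gp$mean_rho, 0)
  # perfect-rank sanity: identical target and coordinate
  maps2 <- maps
  maps2$sigma_f <- matrix(rep(maps$y, each = 8), 8)
  maps2$sigma_b <- maps2$sigma_f
  g2 <- within_region_gradient(maps2, region, target = "width")
  expect_equal(g2$rho, rep(1, 8), tolerance = 1e-12)
})

test_that("without planted gradients the width map shows none", {
  rhos <- vapply(1:10, function(s) {
    vol <- simulate_volume(
      grid_dims = c(9, 17, 9), width_gradient = 0, amplitude_gradient = 0,
      config = synthetic_config(n_participants = 6, n_voxels = 2,
                                anticipation_noise_sd = 0.2,
                                localizer_noise_sd = 0.3, seed = 900 + s))
    maps <- run_searchlight(vol, min_reliable = 30, n_shuffles = 2, seed = s)
    within_region_gradient(maps, which(maps$coverage >= 1),
                           target = "width")$mean_rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("a width gradient leaves the fitted amplitude nearly unchanged", {
  # profile-space planting over the moderate width range the similarity
  # profiles occupy: fitted widths track the gradient exactly while the
  # fitted amplitude stays within a narrow band (the L2 penalty shrinks
  # amplitude slightly more for wide, flat profiles; the effect is small
  # here and only grows for widths far beyond this range)
  sig <- seq(1.2, 2.4, length.out = 25)
  fits <- t(vapply(seq_along(sig), function(i) {
    y <- asym_gauss(-4:4, 0.1, -0.01, sig[i], sig[i])
    names(y) <- as.character(-4:4)
    f <- fit_profile(y)
    c(width = (f$sigma_f + f$sigma_b) / 2, A = f$A)
  }, numeric(2)))
  expect_true(all(diff(fits[, "width"]) > 0))
  expect_lt(max(abs(fits[, "width"] / sig - 1)), 0.1)
  expect_gt(cor(fits[, "width"], sig), 0.995)
  expect_lt(diff(range(fits[, "A"])) / 0.1, 0.1)
})

test_that("partial correlation removes an amplitude-mediated width gradient", {
  # width depends only on amplitude; amplitude itself follows y
  set.seed(68)
  n <- 8
  nv <- 100
  yv <- seq_len(nv)
  A <- matrix(rep(yv, each = n), n) + matrix(rnorm(n * nv, 0, 10), n)
  width <- 2 * A + matrix(rnorm(n * nv, 0, 10), n)
  maps <- list(sigma_f = width, sigma_b = width, A = A, b = A * 0,
               g = A * 0, coverage = rep(1L, nv), y = yv, dims = c(nv, 1, 1))
  raw <- within_region_gradient(maps, seq_len(nv), target = "width")
  part <- within_region_gradient(maps, seq_len(nv), target = "width",
                                 control = "A")
  expect_gt(raw$mean_rho, 0.5)
  expect_lt(abs(part$mean_rho), 0.15)
})

test_that("across-region hierarchy statistics behave at their anchors", {
  set.seed(69)
  n <- 6
  nv <- 50
  maps <- list(sigma_f = matrix(rnorm(n * nv, 2, 0.1), n),
               sigma_b = matrix(rnorm(n * nv, 2, 0.1), n),
               A = matrix(1, n, nv), b = matrix(0, n, nv),
               g = matrix(0, n, nv), coverage = rep(1L, nv),
               y = rep(1, nv), dims = c(nv, 1, 1))
  regions <- split(seq_len(nv), rep(1:5, each = 10))
  names(regions) <- paste0("R", 1:5)
  # plant strictly increasing region means for every participant
  for (k in 1:5) maps$sigma_f[, regions[[k]]] <-
    maps$sigma_f[, regions[[k]]] + k
  for (k in 1:5) maps$sigma_b[, regions[[k]]] <-
    maps$sigma_b[, regions[[k]]] + k
  res <- across_region_hierarchy(maps, regions, target = "width")
  expect_equal(res$rho, rep(1, n))
  expect_lt(res$p, 0.001)
  regions$R3 <- integer(0)
  expect_error(across_region_hierarchy(maps, regions), "R3")
})
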