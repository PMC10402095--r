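test_that("trial_profile peaks at the cue for orthogonal templates", {
  set.seed(31)
  # build near-orthogonal templates and take the cue pattern to be its own
  # template row
  tm <- make_templates(16, 4000)
  path <- 0:7
  prof <- trial_profile(tm[1, ], tm, path, cue = 0)
  expect_equal(unname(prof["0"]), 1, tolerance = 1e-12)
  expect_lt(max(abs(prof[names(prof) != "0"])), 0.1)
  expect_identical(unname(prof["-4"]), unname(prof["4"]))
})

test_that("trial_profile arranges the planted ordering at zero noise", {
  cfg <- synthetic_config(n_participants = 3, n_voxels = 2000,
                          localizer_noise_sd = 0, anticipation_noise_sd = 0,
                          seed = 32)
  st <- synthetic_study(cfg)
  tt <- st$trial_types
  t <- 5
  path <- st$designs[[tt$map[t]]][[tt$path[t]]]
  tm <- heldout_templates(st$localizer, seq_len(2000), 1)
  prof <- trial_profile(st$anticipation[1, t, ], tm, path, tt$cue[t])
  w <- profile_weights(cfg$profile)
  # rank order of the 8 distinct similarity values matches the planted
  # mixing weights
  expect_identical(order(prof[as.character(-3:4)]), order(w))
})

test_that("trial_profile names the offending environment on zero variance", {
  tm <- matrix(rnorm(16 * 30), 16, 30)
  tm[3, ] <- 0                      # environment id 2 is constant
  expect_error(trial_profile(rnorm(30), tm, 0:7, cue = 2), "environment 2")
})

test_that("participant_profile averages and cancels as expected", {
  set.seed(33)
  v <- rnorm(9)
  names(v) <- as.character(-4:4)
  m <- rbind(v, v, v)
  expect_equal(participant_profile(m), v, tolerance = 1e-12)
  expect_equal(unname(participant_profile(rbind(v, -v))), rep(0, 9),
               tolerance = 1e-12)
  expect_error(participant_profile(m, participant = c(1, 1, 2)),
               "multiple participants")
})

test_that("profiles are invariant to template scaling", {
  set.seed(34)
  tm <- make_templates(16, 300)
  x <- rnorm(300)
  p1 <- trial_profile(x, tm, 0:7, cue = 3)
  p2 <- trial_profile(x, tm * 7.5, 0:7, cue = 3)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("uncued profiles permute the same distinct values as cued", {
  st <- synthetic_study(tiny_config(seed = 35))
  cued <- study_profiles(st, ordering = "cued")
  unc <- study_profiles(st, ordering = "uncued")
  # per participant the multiset of 8 distinct values must agree up to
  # trial-type averaging; check at the single-trial level instead
  tm <- heldout_templates(st$localizer, seq_len(200), 1)
  tt <- st$trial_types
  t <- 3
  cued_path <- st$designs[[tt$map[t]]][[tt$path[t]]]
  other <- setdiff(c("green", "blue"), tt$path[t])
  uncued_path <- st$designs[[tt$map[t]]][[other]]
  pc <- trial_profile(st$anticipation[1, t, ], tm, cued_path, tt$cue[t])
  pu <- trial_profile(st$anticipation[1, t, ], tm, uncued_path, tt$cue[t])
  expect_equal(sort(pc[as.character(-3:4)]), sort(pu[as.character(-3:4)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(unname(pc["0"]), unname(pu["0"]))
  # and the averaged baselines agree between orderings (same correlations)
  expect_equal(cued$baseline, unc$baseline, tolerance = 1e-12)
})

test_that("different_map_baseline hits its closed-form anchors", {
  set.seed(36)
  tm_other <- make_templates(8, 3000)
  # cue pattern equal to the other-map mean template
  ref <- colMeans(tm_other)
  expect_equal(different_map_baseline(rbind(ref), tm_other), 1,
               tolerance = 1e-12)
  # cue pattern orthogonalized against every other-map template
  x <- rnorm(3000)
  x <- stats::resid(lm(x ~ t(tm_other)))
  b <- different_map_baseline(rbind(x), tm_other)
  expect_lt(abs(b), 1e-10)
})

test_that("baseline lies below the cue-point similarity in a default study", {
  st <- synthetic_study(tiny_config(seed = 37))
  prof <- study_profiles(st)
  expect_true(all(abs(prof$baseline) < prof$profiles[, "0"]))
})

test_that("the vectorized study path equals the composed per-trial path", {
  st <- synthetic_study(tiny_config(seed = 38))
  prof <- study_profiles(st, ordering = "cued")
  tt <- st$trial_types
  p <- 2
  tm <- heldout_templates(st$localizer, seq_len(200), p)
  trials <- t(vapply(seq_len(nrow(tt)), function(t) {
    path <- st$designs[[tt$map[t]]][[tt$path[t]]]
    trial_profile(st$anticipation[p, t, ], tm, path, tt$cue[t])
  }, numeric(9)))
  expect_equal(unname(participant_profile(trials)),
               unname(prof$profiles[p, ]), tolerance = 1e-10)
  base <- mean(vapply(seq_len(nrow(tt)), function(t) {
    other_envs <- if (tt$map[t] == "A") 9:16 else 1:8
    cor(st$anticipation[p, t, ], colMeans(tm[other_envs, ]))
  }, numeric(1)))
  expect_equal(base, prof$baseline[p], tolerance = 1e-10)
})
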