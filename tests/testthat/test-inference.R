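test_that("identical noiseless Gaussian profiles give near-zero LOO error", {
  y <- asym_gauss(-4:4, 0.05, -0.005, 1.5, 2.5)
  P <- matrix(rep(y, each = 6), 6, 9,
              dimnames = list(NULL, as.character(-4:4)))
  expect_lt(loo_group_error(P), 1e-6)
  expect_lt(loo_group_error(P, include_cue = FALSE), 1e-6)
})

test_that("the two-participant LOO error matches a hand oracle", {
  set.seed(51)
  v <- rnorm(9, 0, 0.1)
  v[1] <- v[9]
  P <- rbind(v, -v)
  colnames(P) <- as.character(-4:4)
  obs <- loo_group_error(P)
  # direct oracle: fit each row, score on the other
  sse_on <- function(train, test) {
    f <- fit_profile(train)
    sum((test - asym_gauss(-4:4, f$A, f$b, f$sigma_f, f$sigma_b))^2)
  }
  names(v) <- as.character(-4:4)
  mv <- -v
  names(mv) <- as.character(-4:4)
  oracle <- mean(c(sse_on(mv, v), sse_on(v, mv)))
  expect_equal(obs, oracle, tolerance = 1e-10)
})

test_that("LOO error is invariant to participant ordering", {
  set.seed(52)
  P <- null_profiles(8)
  expect_equal(loo_group_error(P), loo_group_error(P[sample(8), ]),
               tolerance = 1e-9)
})

test_that("shuffled_null is deterministic and validates input", {
  set.seed(53)
  P <- null_profiles(6)
  n1 <- shuffled_null(P, n_shuffles = 50, seed = 9)
  n2 <- shuffled_null(P, n_shuffles = 50, seed = 9)
  expect_identical(n1$errors, n2$errors)
  expect_error(shuffled_null(P, n_shuffles = 0), "n_shuffles")
  expect_length(n1$errors, 50)
  expect_true(all(n1$errors >= 0))
})

test_that("permutation_result implements the fraction and R-squared contracts", {
  res <- permutation_result(2.5, c(1, 2, 3, 4))
  expect_equal(res$p, 0.5)
  expect_equal(res$r_squared, 0)
  expect_equal(permutation_result(0.5, c(1, 2, 3, 4))$p, 0)
  expect_error(permutation_result(1, numeric(0)), "empty")
  expect_error(permutation_result(1, c(0, 0)), "zero")
  # smoothed variant
  expect_equal(permutation_result(2.5, c(1, 2, 3, 4), smooth = TRUE)$p, 3 / 5)
  # sign property on random data
  set.seed(54)
  P <- null_profiles(6)
  obs <- loo_group_error(P)
  nd <- shuffled_null(P, n_shuffles = 100, seed = 2)
  r <- permutation_result(obs, nd)
  expect_identical(r$r_squared > 0, r$observed_error < mean(nd$errors))
})

test_that("structured profiles are detected with high power", {
  hits <- vapply(1:20, function(s) {
    set.seed(700 + s)
    y <- asym_gauss(-4:4, 0.15, -0.02, 1.5, 2.5)
    P <- matrix(rep(y, each = 12), 12, 9,
                dimnames = list(NULL, as.character(-4:4)))
    P <- P + matrix(rnorm(12 * 9, 0, 0.02), 12, 9)
    P[, "-4"] <- P[, "4"]
    obs <- loo_group_error(P)
    nd <- shuffled_null(P, n_shuffles = 200, seed = s)
    permutation_result(obs, nd)$p
  }, numeric(1))
  expect_gte(mean(hits < 0.05), 0.95)
})

test_that("cued_vs_uncued_test is symmetric and sign-consistent", {
  set.seed(55)
  P <- null_profiles(8)
  res <- cued_vs_uncued_test(P, P, n_shuffles = 200, seed = 1)
  expect_equal(res$delta_obs, 0)
  expect_gt(res$p, 0.2)
  expect_lt(res$p, 0.8)

  Q <- null_profiles(8)
  a <- cued_vs_uncued_test(P, Q, n_shuffles = 10, seed = 2)
  b <- cued_vs_uncued_test(Q, P, n_shuffles = 10, seed = 2)
  expect_equal(a$delta_obs, -b$delta_obs, tolerance = 1e-12)
  expect_error(cued_vs_uncued_test(P, Q[1:5, ], n_shuffles = 10),
               "same participants")
})

test_that("parameter group tests cover the degenerate and analytic cases", {
  fits <- data.frame(participant = 1:32,
                     A = rnorm(32, 0.05, 0.01),
                     b = rnorm(32, -0.01, 0.005),
                     sigma_f = rep(1.5, 32), sigma_b = rep(1.5, 32))
  base <- rep(0, 32)
  res <- parameter_group_tests(fits, base)
  # simulated N(0.05, 0.01^2): expected t ~ 0.05/(0.01/sqrt(32)) ~ 28,
  # rejection at alpha = 0.001 essentially certain
  expect_lt(res$amplitude$p, 0.001)
  expect_equal(res$widths$p, 1)
  expect_equal(res$widths$V, 0)

  fits2 <- fits
  fits2$A <- 0.1         # zero variance of A - baseline
  expect_error(parameter_group_tests(fits2, base), "zero variance")

  fits3 <- fits
  fits3$sigma_f <- fits3$sigma_f + rnorm(32, 0, 0.2)
  expect_warning(parameter_group_tests(fits3, base, permutation_p = 0.5),
                 "not significant")
})

test_that("applying one fixed permutation to all participants leaves the null law unchanged", {
  set.seed(56)
  P <- null_profiles(8)
  dcols <- as.character(-3:4)
  perm <- sample(8)
  V <- P[, dcols]
  Vp <- V[, perm]
  P2 <- profiles_from_distinct(Vp)
  n1 <- shuffled_null(P, n_shuffles = 300, seed = 3)$errors
  n2 <- shuffled_null(P2, n_shuffles = 300, seed = 4)$errors
  ks <- suppressWarnings(stats::ks.test(n1, n2))
  expect_gt(ks$p.value, 0.01)
})
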