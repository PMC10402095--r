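# Independent oracles used across tests. These deliberately avoid the
# package's own computation paths.

# all permutations of v as a matrix (one per row)
all_perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]))
  }))
}

# brute-force neighbor lookup on a circular 8-path, independent of neighbor()
bf_neighbor <- function(path, cue, d) {
  pos <- which(path == cue)
  path[((pos - 1 + d) %% 8) + 1]
}

# count blue orderings (for green fixed at 0..7) satisfying the +/-1,+/-2
# distinctness constraint, by vectorized enumeration in position space
bf_count_valid_orders <- function() {
  P <- all_perms(1:8)                  # position -> env index (1-based)
  n <- nrow(P)
  Pinv <- matrix(0L, n, 8)
  Pinv[cbind(rep(seq_len(n), 8), c(P))] <- rep(1:8, each = n)
  ok <- rep(TRUE, n)
  for (d in c(-2L, -1L, 1L, 2L)) {
    for (e in 1:8) {
      # blue's d-step neighbor of env e vs green's (identity order)
      pos <- ((Pinv[, e] - 1L + d) %% 8L) + 1L
      nb_blue <- P[cbind(seq_len(n), pos)]
      nb_green <- ((e - 1L + d) %% 8L) + 1L
      ok <- ok & (nb_blue != nb_green)
    }
  }
  sum(ok)
}

# dense grid-search oracle for the penalized asymmetric Gaussian objective:
# every 4-D grid point (A, b, sigma_f, sigma_b) is evaluated exactly (the sum
# over profile points is expanded in b for speed but no grid point is
# skipped); zoom stages re-grid around the running argmin
bf_grid_fit_pass <- function(y, d, penalty, A_grid, b_grid, sf_grid, sb_grid) {
  best <- list(objective = Inf)
  m <- length(y)
  nb <- length(b_grid)
  for (sf in sf_grid) {
    for (sb in sb_grid) {
      s <- ifelse(d < 0, sb, sf)
      g <- exp(-d^2 / (2 * s^2))
      Rm <- y - outer(g, A_grid)                   # m x |A|
      s1 <- colSums(Rm^2)
      s2 <- colSums(Rm)
      # SSE(A, b) = sum_d (Rm[, A] - b)^2, expanded in b
      sse <- outer(s1, rep(1, nb)) - 2 * outer(s2, b_grid) +
        m * matrix(b_grid^2, length(A_grid), nb, byrow = TRUE)
      obj <- sse + penalty * outer(A_grid^2, b_grid^2, `+`)
      mm <- which(obj == min(obj), arr.ind = TRUE)[1, ]
      if (obj[mm[1], mm[2]] < best$objective) {
        best <- list(objective = obj[mm[1], mm[2]], A = A_grid[mm[1]],
                     b = b_grid[mm[2]], sigma_f = sf, sigma_b = sb)
      }
    }
  }
  best
}

bf_grid_fit <- function(y, d, penalty = 0.01, zoom = 2) {
  A_grid <- seq(-0.6, 0.6, length.out = 61)
  b_grid <- seq(-0.3, 0.3, length.out = 41)
  s_grid <- exp(seq(log(0.05), log(10), length.out = 36))
  best <- bf_grid_fit_pass(y, d, penalty, A_grid, b_grid, s_grid, s_grid)
  for (z in seq_len(zoom)) {
    stepA <- diff(A_grid)[1]
    stepb <- diff(b_grid)[1]
    A_grid <- seq(best$A - 2 * stepA, best$A + 2 * stepA, length.out = 21)
    b_grid <- seq(best$b - 2 * stepb, best$b + 2 * stepb, length.out = 21)
    zf <- function(s) exp(seq(log(s) - 0.25 / z, log(s) + 0.25 / z,
                              length.out = 15))
    best <- bf_grid_fit_pass(y, d, penalty, A_grid, b_grid,
                             pmin(zf(best$sigma_f), 10),
                             pmin(zf(best$sigma_b), 10))
  }
  best
}

bf_grid_fit_objective <- function(y, d, penalty = 0.01) {
  bf_grid_fit(y, d, penalty, zoom = 1)$objective
}

# build a profile matrix (participants x 9, columns "-4".."4") from a
# participant x 8 matrix of distinct values at offsets -3..4
profiles_from_distinct <- function(V) {
  stopifnot(ncol(V) == 8)
  out <- cbind(V[, 8], V)
  colnames(out) <- as.character(-4:4)
  out
}

# random exchangeable null profiles
null_profiles <- function(n, sd = 0.05) {
  profiles_from_distinct(matrix(rnorm(n * 8, sd = sd), n, 8))
}

# a small, fast study configuration for end-to-end unit tests
tiny_config <- function(seed = 1, ...) {
  synthetic_config(n_participants = 8, n_voxels = 200, seed = seed, ...)
}
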