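#' Across-participant environment reliability
#'
#' For each voxel, correlates every participant's 16-element environment
#' tuning vector with the average tuning vector of the remaining
#' participants, and averages the correlation over the held-out participants.
#' Undefined correlations (constant vectors) are excluded from the average
#' rather than coerced to zero; their count is recorded.
#'
#' @param localizer array `participant x environment x voxel` of betas.
#' @return numeric vector of per-voxel reliability scores (NA where every
#'   term was undefined), with attribute `"n_undefined"`.
#' @export
environment_reliability <- function(localizer) {
  stopifnot(length(dim(localizer)) == 3L)
  n <- dim(localizer)[1]
  ne <- dim(localizer)[2]
  if (n < 3) stop("need at least 3 participants")
  total <- apply(localizer, c(2, 3), sum)
  rsum <- numeric(dim(localizer)[3])
  rcount <- integer(dim(localizer)[3])
  n_undef <- 0L
  for (p in seq_len(n)) {
    X <- array(localizer[p, , ], dim(localizer)[2:3])  # 16 x V
    M <- (total - X) / (n - 1)                 # mean of the others
    sx <- colSums(X); sxx <- colSums(X^2)
    sm <- colSums(M); smm <- colSums(M^2)
    sxm <- colSums(X * M)
    vx <- ne * sxx - sx^2
    vm <- ne * smm - sm^2
    den2 <- vx * vm
    ok <- den2 > .Machine$double.eps * pmax(ne * sxx, 1) * pmax(ne * smm, 1)
    r <- rep(NA_real_, length(sx))
    r[ok] <- (ne * sxm[ok] - sx[ok] * sm[ok]) / sqrt(den2[ok])
    n_undef <- n_undef + sum(!ok)
    rsum[ok] <- rsum[ok] + r[ok]
    rcount[ok] <- rcount[ok] + 1L
  }
  if (n_undef > 0)
    warning(n_undef, " undefined (constant-vector) correlation terms excluded")
  out <- ifelse(rcount > 0, rsum / pmax(rcount, 1L), NA_real_)
  structure(out, n_undefined = n_undef)
}

#' Environment-reliable voxels within a mask
#'
#' Selects voxels whose reliability score is at or above the threshold
#' (inclusive), intersected with a mask.
#'
#' @param reliability per-voxel reliability vector.
#' @param mask voxel indices or logical mask; `NULL` means all voxels.
#' @param threshold inclusion cutoff (default 0.1).
#' @return integer voxel indices of the conjunction ROI (attribute `"size"`).
#' @export
conjunction_roi <- function(reliability, mask = NULL, threshold = 0.1) {
  r <- as.numeric(reliability)
  idx <- seq_along(r)
  if (!is.null(mask)) {
    idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
    if (length(idx) == 0) stop("mask is empty")
  }
  roi <- idx[!is.na(r[idx]) & r[idx] >= threshold]
  if (length(roi) == 0)
    warning("no voxels pass the reliability threshold")
  structure(roi, size = length(roi))
}

#' Held-out environment templates
#'
#' The template for an environment is the average beta pattern over all
#' participants except the held-out one, restricted to an ROI, so templates
#' never contain the held-out participant's data.
#'
#' @param localizer array `participant x environment x voxel`.
#' @param roi voxel indices.
#' @param held_out participant index to exclude.
#' @return matrix `environment x length(roi)`.
#' @export
heldout_templates <- function(localizer, roi, held_out) {
  n <- dim(localizer)[1]
  if (!(held_out %in% seq_len(n))) stop("held_out participant not in study")
  if (n - 1 < 1) stop("no remaining participants to average")
  colMeans(localizer[-held_out, , roi, drop = FALSE])
}

#' Minimum-cluster filter for volumetric reliability maps
#'
#' Keeps only voxels belonging to a 6-connected cluster of at least
#' `min_size` voxels; intended for whole-volume reliability maps, off by
#' default in ROI mode.
#'
#' @param keep logical vector over the grid (TRUE = above threshold).
#' @param dims grid dimensions (nx, ny, nz).
#' @param min_size minimum cluster size (default 10).
#' @return logical vector with small clusters removed.
#' @export
cluster_filter <- function(keep, dims, min_size = 10) {
  stopifnot(length(keep) == prod(dims))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  lab <- integer(length(keep))
  out <- logical(length(keep))
  nbr_offsets <- function(i) {
    z <- (i - 1) %/% (nx * ny)
    y <- ((i - 1) %% (nx * ny)) %/% nx
    x <- (i - 1) %% nx
    res <- integer(0)
    if (x > 0)      res <- c(res, i - 1L)
    if (x < nx - 1) res <- c(res, i + 1L)
    if (y > 0)      res <- c(res, i - nx)
    if (y < ny - 1) res <- c(res, i + nx)
    if (z > 0)      res <- c(res, i - nx * ny)
    if (z < nz - 1) res <- c(res, i + nx * ny)
    res
  }
  cur <- 0L
  for (start in which(keep)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    members <- start
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      for (j in nbr_offsets(i)) {
        if (keep[j] && lab[j] == 0L) {
          lab[j] <- cur
          queue <- c(queue, j)
          members <- c(members, j)
        }
      }
    }
    if (length(members) >= min_size) out[members] <- TRUE
  }
  out
}
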