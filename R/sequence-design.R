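#' Circular step lookup along a path
#'
#' Returns the environment `d` steps from `cue` along a circular path of
#' eight environments. Positive offsets step forward (successors), negative
#' offsets backward (predecessors); offsets +4 and -4 address the same
#' environment.
#'
#' @param path integer vector of 8 environment ids, in path order (circular).
#' @param cue environment id present on `path`.
#' @param d integer step offset (vectorized), typically in -4..4.
#' @return environment id(s) at the requested offset(s).
#' @export
neighbor <- function(path, cue, d) {
  stopifnot(length(path) == 8L, anyDuplicated(path) == 0L)
  pos <- match(cue, path)
  if (is.na(pos)) stop("cue environment ", cue, " is not on the path")
  path[((pos - 1L + as.integer(d)) %% 8L) + 1L]
}

#' Check the path-distinctness constraint of a map design
#'
#' The green and blue paths of a map must be maximally distinct: for every
#' environment, its one- and two-step neighbors (in both directions) must
#' differ between the two paths.
#'
#' @param design a map design as returned by [generate_map_design()], i.e. a
#'   list with integer vectors `green` and `blue` over the same 8 environments.
#' @return `TRUE`/`FALSE`; attribute `"violations"` holds a data frame of
#'   offending (environment, offset) pairs.
#' @export
check_path_constraint <- function(design) {
  green <- design$green
  blue <- design$blue
  if (!setequal(green, blue))
    stop("green and blue paths must permute the same 8 environments")
  offs <- c(-2L, -1L, 1L, 2L)
  viol <- list()
  for (e in green) {
    for (d in offs) {
      if (neighbor(blue, e, d) == neighbor(green, e, d))
        viol[[length(viol) + 1L]] <- c(env = e, d = d)
    }
  }
  ok <- length(viol) == 0L
  v <- if (ok) data.frame(env = integer(0), d = integer(0))
       else as.data.frame(do.call(rbind, viol))
  structure(ok, violations = v)
}

# coincidences between the two paths at the offsets the hard constraint
# leaves free (|d| = 3 and the shared four-step neighbor)
far_coincidences <- function(design) {
  s <- 0L
  for (e in design$green) {
    for (d in c(-3L, 3L, 4L)) {
      if (neighbor(design$blue, e, d) == neighbor(design$green, e, d))
        s <- s + 1L
    }
  }
  s
}

# rejection-sample a position permutation pi such that blue = green[pi]
# satisfies the constraint for any green order (validity depends only on pi).
# With maximize_distinctness the sampler also requires the minimal achievable
# number of far-offset coincidences (2 on an 8-cycle; zero is impossible),
# making the two orderings as distinct as the circular geometry allows.
sample_valid_reindex <- function(max_tries = 100000L,
                                 maximize_distinctness = TRUE) {
  for (i in seq_len(max_tries)) {
    pi <- sample.int(8L)
    d <- list(green = 0:7, blue = (0:7)[pi])
    if (!isTRUE(c(check_path_constraint(d)))) next
    if (maximize_distinctness && far_coincidences(d) > 2L) next
    return(pi)
  }
  stop("no valid reindexing found")  # unreachable: valid orders exist
}

#' Generate a constraint-satisfying green/blue path pair
#'
#' Samples a green ordering of the given environments and derives the blue
#' path by a position reindexing sampled by rejection until the
#' two-step-distinctness constraint holds. The reindexing can be supplied so
#' the same green-to-blue shuffle is reused across maps.
#'
#' @param envs 8 distinct environment ids.
#' @param seed optional integer seed (design is deterministic given seed).
#' @param reindex optional position permutation (integer vector, a permutation
#'   of 1..8) to reuse across maps; sampled if `NULL`.
#' @param map map label, "A" or "B".
#' @return list with `map`, `green`, `blue`, `reindex`, `seed`.
#' @export
generate_map_design <- function(envs, seed = NULL, reindex = NULL, map = "A") {
  envs <- as.integer(envs)
  stopifnot(length(envs) == 8L, anyDuplicated(envs) == 0L)
  if (!is.null(seed)) set.seed(seed)
  green <- sample(envs)
  if (is.null(reindex)) reindex <- sample_valid_reindex()
  blue <- green[reindex]
  design <- list(map = map, green = green, blue = blue,
                 reindex = as.integer(reindex), seed = seed)
  stopifnot(isTRUE(c(check_path_constraint(design))))
  design
}

#' @rdname generate_map_design
#' @param design a map design.
#' @param path path to a JSON file.
#' @export
write_design_json <- function(design, path) {
  jsonlite::write_json(design[c("map", "green", "blue", "reindex", "seed")],
                       path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname generate_map_design
#' @export
read_design_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  d$green <- as.integer(d$green)
  d$blue <- as.integer(d$blue)
  d
}
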