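#' Group accuracy versus chance
#'
#' Per-participant accuracy over all trials, tested against chance (50%)
#' with a two-sided one-sample t-test.
#'
#' @param trials trial-record data frame with `participant` and `correct`.
#' @return list with `accuracy` (per participant), `mean`, `sd`, `t`, `df`,
#'   `p`.
#' @export
accuracy_vs_chance <- function(trials) {
  acc <- tapply(trials$correct, trials$participant, mean)
  if (length(acc) < 2) stop("need at least 2 participants")
  if (sd(acc) == 0)
    stop("zero variance of accuracies; t-test undefined")
  tt <- t.test(acc, mu = 0.5)
  list(accuracy = acc, mean = mean(acc), sd = sd(acc),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Per-participant response-time slopes over steps into the future
#'
#' Ordinary least squares of RT (seconds) on steps-into-the-future (1..4),
#' per participant, using correct trials only.
#'
#' @param trials trial-record data frame with `participant`, `steps`,
#'   `correct`, `rt`.
#' @return data frame with `participant`, `slope` (s per step), `intercept`,
#'   `n_trials`, `ok` (FALSE where step variation was insufficient; such
#'   participants are excluded downstream with a warning).
#' @export
rt_slopes <- function(trials) {
  ids <- sort(unique(trials$participant))
  out <- lapply(ids, function(p) {
    sub <- trials[trials$participant == p & trials$correct, , drop = FALSE]
    if (nrow(sub) < 2 || length(unique(sub$steps)) < 2)
      return(data.frame(participant = p, slope = NA_real_,
                        intercept = NA_real_, n_trials = nrow(sub),
                        ok = FALSE))
    cf <- coef(lm(rt ~ steps, data = sub))
    data.frame(participant = p, slope = unname(cf["steps"]),
               intercept = unname(cf["(Intercept)"]),
               n_trials = nrow(sub), ok = TRUE)
  })
  out <- do.call(rbind, out)
  if (any(!out$ok))
    warning(sum(!out$ok), " participant(s) lack step variation on correct ",
            "trials; flagged and excluded downstream")
  out
}

#' Brain-behavior linkage
#'
#' Spearman rank correlation between a per-participant fitted parameter
#' (e.g. the asymptote) and the per-participant response-time slope.
#'
#' @param parameter numeric vector, one value per participant.
#' @param slopes numeric vector of RT slopes, matched to `parameter`.
#' @return list with `rho`, `p`, `n`.
#' @export
brain_behavior_correlation <- function(parameter, slopes) {
  keep <- complete.cases(parameter, slopes)
  parameter <- parameter[keep]
  slopes <- slopes[keep]
  n <- length(parameter)
  if (n < 4) stop("need at least 4 matched participants")
  if (sd(parameter) == 0 || sd(slopes) == 0)
    stop("constant input; Spearman correlation undefined")
  ct <- suppressWarnings(cor.test(parameter, slopes, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Write trial records to TSV
#'
#' Columns: participant, map, path, cue, steps, correct, rt (seconds).
#'
#' @param trials trial-record data frame.
#' @param path output file.
#' @export
write_trials_tsv <- function(trials, path) {
  write.table(trials, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_tsv
#' @export
read_trials_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
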