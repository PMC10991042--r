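#' Traditional permutation test for an AB series
#'
#' The classical two-group permutation test, applied to the two phases while
#' ignoring serial dependency: the non-missing outcomes are freely reassigned
#' to the phase labels and the p-value computed as in
#' [permutation_pvalue()] (exhaustive when feasible). Included as a benchmark
#' -- with autocorrelated data its type-I error rate is inflated, which is
#' what the distancing test corrects.
#'
#' @inheritParams pdt
#' @return A list of class `randomization_test` with `observed_statistic`,
#'   `p.value`, `n_randomizations`, `exhaustive`, `method`, `sided`.
#' @examples
#' perm_test(make_equidistant(fitnet_plus()), seed = 1)
#' @export
perm_test <- function(series, statistic = c("mean", "median"),
                      n_permutations = 10000L,
                      sided = c("two", "greater", "less"), seed = NULL) {
  stopifnot(inherits(series, "ab_series"))
  statistic <- match.arg(statistic)
  sided <- match.arg(sided)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  res <- permutation_pvalue(series$y, as.character(series$phase), statistic,
                            n_permutations, sided)
  structure(list(observed_statistic = res$observed, p.value = res$p,
                 n_randomizations = res$n_used, exhaustive = res$exhaustive,
                 method = "traditional permutation test",
                 statistic = statistic, sided = sided),
            class = "randomization_test")
}

#' Single-case randomization test over intervention start points
#'
#' For a single-case *experimental* design, where the start of phase B was
#' randomized, the reference distribution is not free reshuffling but the set
#' of statistics obtained from every admissible start point of phase B. This
#' enumerates all divisions of the observation sequence into a leading
#' A segment and a trailing B segment with at least `n1_min` observations in
#' each, computes the phase difference for every division, and reports the
#' proportion of divisions (the observed one included) whose statistic is as
#' or more extreme than the observed one.
#'
#' By default divisions are taken over the sequence of non-missing
#' observations; `positions = "markers"` instead divides the equidistant
#' marker grid (phase statistics still use non-missing values only). The two
#' conventions differ in the number of admissible randomizations when the
#' series has missing values.
#'
#' @inheritParams pdt
#' @param n1_min minimum number of observations per phase.
#' @param sided default `"greater"`: one-sided in the hypothesized improvement
#'   direction, A above B (e.g. symptom decline after treatment).
#' @param positions `"observations"` (default) or `"markers"`, see Details.
#' @return A `randomization_test` (see [perm_test()]); p is at least
#'   1/(number of admissible randomizations).
#' @examples
#' scrt(make_equidistant(fitnet_plus()), n1_min = 1)
#' @export
scrt <- function(series, n1_min = 1L, statistic = c("mean", "median"),
                 sided = c("greater", "less", "two"),
                 positions = c("observations", "markers")) {
  stopifnot(inherits(series, "ab_series"))
  statistic <- match.arg(statistic)
  sided <- match.arg(sided)
  positions <- match.arg(positions)
  n1_min <- as.integer(n1_min)
  stopifnot(n1_min >= 1L)

  if (positions == "observations") {
    keep <- !is.na(series$y)
    v <- series$y[keep]
    obs_nA <- sum(series$phase[keep] == "A")
  } else {
    v <- series$y
    obs_nA <- sum(series$phase == "A")
  }
  n <- length(v)
  splits <- seq.int(n1_min, n - n1_min)
  if (length(splits) < 2L)
    stop("too few admissible start points (need at least 2)")
  if (!obs_nA %in% splits)
    stop("observed phase division not admissible under n1_min = ", n1_min)

  stat_at <- function(j) {
    a <- v[seq_len(j)]; b <- v[seq.int(j + 1L, n)]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0L || length(b) == 0L) return(NA_real_)
    if (statistic == "mean") mean(a) - mean(b) else
      stats::median(a) - stats::median(b)
  }
  stats_all <- vapply(splits, stat_at, 0)
  ok <- !is.na(stats_all)
  stats_all <- stats_all[ok]
  obs <- stat_at(obs_nA)
  eps <- 1e-8 * (abs(obs) + 1)
  cnt <- switch(sided,
    two = sum(abs(stats_all) >= abs(obs) - eps),
    greater = sum(stats_all >= obs - eps),
    less = sum(stats_all <= obs + eps))
  structure(list(observed_statistic = obs, p.value = cnt / sum(ok),
                 n_randomizations = sum(ok), exhaustive = TRUE,
                 method = sprintf("single-case randomization test (%s)", positions),
                 statistic = statistic, sided = sided),
            class = "randomization_test")
}

#' @export
print.randomization_test <- function(x, digits = 3, ...) {
  cat(x$method, "\n")
  cat(sprintf("statistic: phase %s difference (A - B), %s-sided\n",
              x$statistic, x$sided))
  cat(sprintf("observed statistic: %.*f\n", digits, x$observed_statistic))
  cat(sprintf("p = %.*f (%d %s randomizations)\n", digits, x$p.value,
              x$n_randomizations,
              if (x$exhaustive) "exhaustive" else "Monte Carlo"))
  invisible(x)
}
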