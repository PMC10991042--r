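#' Simulate a single-case AB series from an interrupted time-series model
#'
#' Generates data from the simplified two-phase regression model
#' \deqn{Y_t = b_0 + b_2 D_t + \varepsilon_t,}
#' where \eqn{D_t} is 0 during phase A and 1 during phase B, and the errors
#' follow a first-order autoregressive process
#' \eqn{\varepsilon_t = \phi\,\varepsilon_{t-1} + z_t} with standard normal
#' innovations and a 100-step burn-in (so `ar1 = 0` reduces to iid standard
#' normal noise). Innovations have unit variance, so the marginal error
#' variance is \eqn{1/(1-\phi^2)} -- they are not re-normalized. The baseline
#' length is drawn uniformly from `n1_limit` to `n - n1_limit`, emulating a
#' randomized intervention start.
#'
#' Linear trend coefficients `b1` (phase-A slope) and `b3` (extra phase-B
#' slope) are accepted as hooks and default to 0; the package's validation
#' profile concerns trend-free data.
#'
#' @param n total number of observations.
#' @param b2 treatment effect: mean level shift in phase B (SD units of the
#'   innovation).
#' @param ar1 autoregressive coefficient, `|ar1| < 1`.
#' @param n1_limit minimum number of observations in either phase.
#' @param b0 intercept.
#' @param b1,b3 trend coefficients (hooks, default 0).
#' @param seed optional integer seed.
#' @return An [ab_series] with time markers `1..n`.
#' @examples
#' s <- simulate_ab_series(30, b2 = 1, ar1 = 0.3, seed = 1)
#' phase_summary(s)
#' @export
simulate_ab_series <- function(n, b2 = 0, ar1 = 0, n1_limit = 5L, b0 = 0,
                               b1 = 0, b3 = 0, seed = NULL) {
  n <- as.integer(n)
  n1_limit <- as.integer(n1_limit)
  if (n < 2L * n1_limit) stop("n must be at least 2 * n1_limit")
  if (abs(ar1) >= 1) stop("|ar1| must be below 1")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  nA <- if (n1_limit == n - n1_limit) n1_limit else
    sample(seq.int(n1_limit, n - n1_limit), 1L)
  burn <- 100L
  z <- stats::rnorm(burn + n)
  if (ar1 == 0) {
    eps <- z[(burn + 1L):(burn + n)]
  } else {
    e <- numeric(burn + n)
    e[1L] <- z[1L]
    for (t in 2L:(burn + n)) e[t] <- ar1 * e[t - 1L] + z[t]
    eps <- e[(burn + 1L):(burn + n)]
  }
  t_idx <- seq_len(n)
  D <- as.numeric(t_idx > nA)
  y <- b0 + b1 * t_idx + b2 * D + b3 * D * (t_idx - nA) + eps
  ab_series(t_idx, ifelse(D == 0, "A", "B"), y)
}

sim_test_p <- function(series, test, b2, alpha, n_permutations, sided, n1_limit) {
  side <- if (sided == "auto") {
    if (b2 > 0) "less" else "greater"   # improvement direction of the cell
  } else sided
  switch(test,
    pdt = pdt(series, n_permutations = n_permutations, sided = side)$p.value,
    traditional = perm_test(series, n_permutations = n_permutations,
                            sided = side)$p.value,
    scrt = scrt(series, n1_min = n1_limit,
                sided = if (side == "two") "two" else side)$p.value,
    stop("unknown test: ", test))
}

#' Rejection rate of a test in one simulation cell
#'
#' Generates `replications` series from [simulate_ab_series()] with the given
#' factor levels, applies the chosen test to each, and returns the proportion
#' of p-values at or below `alpha`. For the distancing test the decision uses
#' the fitted p-value at the favored k. With `b2 = 0` this estimates the
#' type-I error rate; otherwise statistical power.
#'
#' @param test `"pdt"`, `"scrt"` or `"traditional"`.
#' @param n,b2,ar1,n1_limit generator factor levels (see
#'   [simulate_ab_series()]).
#' @param replications Monte Carlo replications.
#' @param alpha significance level; rejection means p <= alpha (the
#'   randomization tests are granular: with 30 observations and
#'   `n1_limit = 5` the smallest attainable start-point p is 1/21, which must
#'   count as a rejection at the 5% level).
#' @param n_permutations permutations per (subset) test; the reduced desk
#'   profile of 1000 keeps a cell in the minutes range.
#' @param sided `"auto"` (one-sided toward the sign of `b2`; `"less"` when
#'   `b2 = 0`), or an explicit `"two"`, `"greater"`, `"less"`.
#' @param seed optional integer seed for the whole cell.
#' @return The rejection proportion (scalar in \eqn{[0, 1]}).
#' @examples
#' rejection_rate("pdt", n = 30, b2 = 0, ar1 = 0, replications = 20,
#'                n_permutations = 200, seed = 1)
#' @export
rejection_rate <- function(test = c("pdt", "scrt", "traditional"),
                           n = 30, b2 = 0, ar1 = 0, n1_limit = 5L,
                           replications = 200L, alpha = 0.05,
                           n_permutations = 1000L, sided = "auto",
                           seed = NULL) {
  test <- match.arg(test)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  rej <- 0L
  for (i in seq_len(replications)) {
    p <- withCallingHandlers(
      sim_test_p(simulate_ab_series(n, b2, ar1, n1_limit), test, b2, alpha,
                 n_permutations, sided, n1_limit),
      warning = function(w) invokeRestart("muffleWarning"))
    if (p <= alpha) rej <- rej + 1L
  }
  rej / replications
}

#' Monte Carlo power study over a factor grid
#'
#' Crosses the factor levels, runs [rejection_rate()] for every cell, test and
#' batch, and returns a tidy table (one row per cell x test x batch). Each
#' batch uses an independent seed substream derived from `seed`, so the study
#' is reproducible and resumable cell by cell. The full validation grid
#' (`ar1` 0/.15/.30/.45/.60, `n` 30/60/90/120, `b2` -2..2, `n1_limit` 5/10;
#' 200 cells, 1000 replications, 5 batches) is expressible but cluster-scale;
#' the defaults are a desk-scale profile.
#'
#' @param ar1,n,b2,n1_limit factor levels (vectors).
#' @param tests which tests to run.
#' @param replications replications per batch.
#' @param batches independent batches per cell (the across-batch spread gives
#'   a confidence interval, see [summarize_power()]).
#' @param alpha,n_permutations,sided passed to [rejection_rate()].
#' @param seed integer master seed.
#' @return A data frame of class `power_study` with the factor columns,
#'   `test`, `batch` and `rejection_rate`.
#' @examples
#' ps <- power_study(ar1 = 0, n = 30, b2 = c(0, 2), replications = 10,
#'                   n_permutations = 200, seed = 1)
#' summarize_power(ps)
#' @export
power_study <- function(ar1 = c(0, 0.15, 0.3, 0.45, 0.6),
                        n = c(30, 60, 90, 120),
                        b2 = c(-2, -1, 0, 1, 2),
                        n1_limit = c(5L, 10L),
                        tests = c("pdt", "scrt", "traditional"),
                        replications = 200L, batches = 1L, alpha = 0.05,
                        n_permutations = 1000L, sided = "auto", seed = 1L) {
  tests <- match.arg(tests, several.ok = TRUE)
  grid <- expand.grid(ar1 = ar1, n = n, b2 = b2, n1_limit = n1_limit,
                      test = tests, batch = seq_len(batches),
                      stringsAsFactors = FALSE)
  grid$rejection_rate <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cell_seed <- as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
    grid$rejection_rate[i] <- rejection_rate(
      grid$test[i], n = grid$n[i], b2 = grid$b2[i], ar1 = grid$ar1[i],
      n1_limit = grid$n1_limit[i], replications = replications, alpha = alpha,
      n_permutations = n_permutations, sided = sided, seed = cell_seed)
  }
  attr(grid, "replications") <- replications
  attr(grid, "alpha") <- alpha
  attr(grid, "seed") <- seed
  class(grid) <- c("power_study", "data.frame")
  grid
}

#' Summarize a power study across batches
#'
#' Mean rejection rate per cell x test with a normal-approximation 95%
#' confidence interval from the across-batch standard error (degenerate with
#' a single batch).
#'
#' @param study a [power_study()] result.
#' @return A data frame with one row per cell x test: `mean`, `lower`,
#'   `upper`, `batches`.
#' @export
summarize_power <- function(study) {
  stopifnot(inherits(study, "power_study"))
  key <- interaction(study$ar1, study$n, study$b2, study$n1_limit, study$test,
                     drop = TRUE)
  parts <- split(seq_len(nrow(study)), key)
  out <- lapply(parts, function(idx) {
    r <- study$rejection_rate[idx]
    m <- mean(r)
    se <- if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else NA_real_
    cbind(study[idx[1L], c("ar1", "n", "b2", "n1_limit", "test")],
          data.frame(mean = m, lower = m - 1.96 * se, upper = m + 1.96 * se,
                     batches = length(r)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$test, out$n1_limit, out$n, out$ar1, out$b2), ]
}

#' Power-curve plot for a study
#'
#' Rejection rate against the treatment effect, one panel per autocorrelation
#' level, colored by test, with 80% and 5% reference lines.
#'
#' @param study a [power_study()] result.
#' @return A ggplot object.
#' @export
plot_power <- function(study) {
  s <- summarize_power(study)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$b2, y = .data$mean,
                                  colour = .data$test)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.1, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = c(0.05, 0.8), linewidth = 0.3) +
    ggplot2::facet_grid(n ~ ar1, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "treatment effect (b2)", y = "rejection proportion",
                  colour = "test") +
    ggplot2::theme_minimal()
}
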