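#' Lag-1 sample autocorrelation
#'
#' Missing entries are removed and the retained values are treated as a
#' regular (consecutive) series; within a distanced subset the retained
#' values are equally spaced by construction, so this is the natural
#' convention there.
#'
#' \deqn{r_1 = \sum_t (x_t - \bar x)(x_{t+1} - \bar x) \big/ \sum_t (x_t - \bar x)^2}
#'
#' @param x numeric vector, `NA` allowed.
#' @return The lag-1 autocorrelation, in \eqn{[-1, 1]}.
#' @examples
#' lag1_autocorrelation(make_equidistant(fitnet_plus())$y)  # ~ 0.724
#' @export
lag1_autocorrelation <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) stop("need at least 3 non-missing values")
  m <- mean(x)
  denom <- sum((x - m)^2)
  if (denom == 0) stop("degenerate series: zero variance")
  n <- length(x)
  sum((x[-n] - m) * (x[-1L] - m)) / denom
}

#' Ljung-Box portmanteau test of serial autocorrelation
#'
#' \deqn{Q = n(n+2) \sum_{j=1}^{L} r_j^2 / (n - j)}
#' compared to an upper-tail chi-square with `lags` degrees of freedom,
#' where \eqn{n} is the number of retained (non-missing) values. The default
#' single lag is what gates the distancing procedure: the relevant question
#' per subset is whether adjacent retained observations are still dependent.
#'
#' @param x numeric vector, `NA` allowed (dropped as in
#'   [lag1_autocorrelation()]).
#' @param lags number of autocorrelation lags entering the statistic.
#' @return A list of class `ljung_box` with elements `n`, `r1`, `statistic`
#'   (Q), `df` and `p.value`.
#' @examples
#' ljung_box(make_equidistant(fitnet_plus())$y)  # Q ~ 20.99, p < .001
#' @export
ljung_box <- function(x, lags = 1L) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < lags + 2L) stop("need at least lags + 2 non-missing values")
  m <- mean(x)
  denom <- sum((x - m)^2)
  if (denom == 0) stop("degenerate series: zero variance")
  js <- seq_len(lags)
  rj <- vapply(js, function(j)
    sum((x[seq_len(n - j)] - m) * (x[seq_len(n - j) + j] - m)) / denom, 0)
  Q <- n * (n + 2) * sum(rj^2 / (n - js))
  structure(list(n = n, r1 = rj[1L], statistic = Q, df = lags,
                 p.value = stats::pchisq(Q, df = lags, lower.tail = FALSE)),
            class = "ljung_box")
}

#' @export
print.ljung_box <- function(x, ...) {
  cat(sprintf("Ljung-Box test: n = %d, r1 = %.3f, Q = %.3f (df = %d), p = %.3g\n",
              x$n, x$r1, x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Combine per-subset dependency diagnostics for one distance k
#'
#' At distance k the series splits into k subsets, each with its own
#' Ljung-Box result. The summary row reports the arithmetic means of the
#' subset lag-1 autocorrelations and Q statistics, and a combined p-value
#' that gates the distancing procedure.
#'
#' Two combination rules are available. `"min"` (default) takes the smallest
#' subset p-value: distancing continues while *any* subset still shows
#' significant autocorrelation, the conservative reading of the stopping rule.
#' `"fisher"` combines the subset p-values with Fisher's method
#' (\eqn{-2\sum \ln p_l} against chi-square with 2k df). For k = 1 both
#' equal the single subset's p-value. P-values are floored at 1e-16 before
#' taking logs.
#'
#' @param results list of [ljung_box] results, one per subset (`NULL` entries,
#'   from subsets too short or too degenerate to test, are skipped).
#' @param k the distance the subsets belong to.
#' @param method `"min"` or `"fisher"`.
#' @return A list with `k`, `n_subsets`, `mean_r1`, `mean_Q`, `combined_p`.
#' @export
combine_dependency <- function(results, k, method = c("min", "fisher")) {
  method <- match.arg(method)
  results <- Filter(Negate(is.null), results)
  if (length(results) == 0L)
    return(list(k = k, n_subsets = 0L, mean_r1 = NA_real_, mean_Q = NA_real_,
                combined_p = NA_real_))
  r1 <- vapply(results, `[[`, 0, "r1")
  Q <- vapply(results, `[[`, 0, "statistic")
  p <- pmax(vapply(results, `[[`, 0, "p.value"), 1e-16)
  combined <- switch(method,
    min = min(p),
    fisher = stats::pchisq(-2 * sum(log(p)), df = 2 * length(p),
                           lower.tail = FALSE))
  list(k = k, n_subsets = length(results), mean_r1 = mean(r1),
       mean_Q = mean(Q), combined_p = combined)
}
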