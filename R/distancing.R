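#' Distanced subsets of an AB series
#'
#' At distance `k`, subset `l` (for `l = 1..k`) retains the time positions
#' `l, l+k, l+2k, ...` of the full equidistant series -- counting from the
#' global start of the series, not restarting at the phase boundary -- so
#' that within each subset adjacent retained observations are `k` time steps
#' apart. The `k` subsets partition the series.
#'
#' @param series an [ab_series].
#' @param k temporal distance, `1 <= k <= nrow(series)`.
#' @return A list of `k` subsets; each is a list with `k`, `l`, `positions`
#'   (time markers), `values` (outcomes, `NA` retained) and `phase`.
#' @examples
#' s <- make_equidistant(fitnet_plus())
#' build_subsets(s, 3)[[1]]$values[1:4]  # 48 43 44 47
#' @export
build_subsets <- function(series, k) {
  stopifnot(inherits(series, "ab_series"))
  n <- nrow(series)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be between 1 and the series length")
  lapply(seq_len(k), function(l) {
    idx <- seq.int(l, n, by = k)
    list(k = k, l = l, positions = series$time[idx],
         values = series$y[idx], phase = as.character(series$phase[idx]))
  })
}

#' Phase difference statistic of one subset
#'
#' The mean (or median) of the subset's non-missing A values minus that of
#' its non-missing B values. Returns `NA` when a phase is empty within the
#' subset (such subsets are excluded from per-k aggregation).
#'
#' @param subset one element of [build_subsets()].
#' @param statistic `"mean"` or `"median"`.
#' @return The phase difference, or `NA`.
#' @export
subset_statistic <- function(subset, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  phase_diff(subset$values, subset$phase, statistic)
}

phase_diff <- function(values, phase, statistic) {
  a <- values[phase == "A" & !is.na(values)]
  b <- values[phase == "B" & !is.na(values)]
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  if (statistic == "mean") mean(a) - mean(b) else
    stats::median(a) - stats::median(b)
}

#' Permutation p-value for a phase difference
#'
#' Non-missing values are reassigned to the phase labels; the p-value is the
#' proportion of reassignments whose statistic is as or more extreme than the
#' observed one (two-sided extremity via absolute value). When the number of
#' distinct assignments `choose(n, nA)` does not exceed `n_permutations` the
#' distribution is enumerated exhaustively (the observed assignment is then
#' one of them, so p >= 1/choose(n, nA)); otherwise `n_permutations` random
#' reassignments are drawn and p is the plain proportion among them.
#'
#' @param values numeric outcomes (`NA` dropped).
#' @param phase phase labels aligned with `values`.
#' @param statistic `"mean"` or `"median"` phase difference.
#' @param n_permutations Monte Carlo sample size / enumeration cutoff.
#' @param sided `"two"`, `"greater"` (A above B) or `"less"`.
#' @param method `"auto"` (enumerate when feasible), `"exhaustive"` (force
#'   enumeration; errors beyond 10^6 assignments) or `"montecarlo"`.
#' @return A list with `p`, `observed`, `exhaustive` and
#'   `n_used` (assignments evaluated).
#' @examples
#' permutation_pvalue(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))$p  # 0.1
#' @export
permutation_pvalue <- function(values, phase, statistic = c("mean", "median"),
                               n_permutations = 10000L,
                               sided = c("two", "greater", "less"),
                               method = c("auto", "exhaustive", "montecarlo")) {
  statistic <- match.arg(statistic)
  sided <- match.arg(sided)
  method <- match.arg(method)
  keep <- !is.na(values)
  v <- values[keep]
  lab <- phase[keep]
  nA <- sum(lab == "A")
  nB <- sum(lab == "B")
  if (nA == 0L || nB == 0L) stop("both phases need a non-missing value")
  obs <- phase_diff(v, lab, statistic)
  if (length(unique(v)) == 1L)
    return(list(p = 1, observed = obs, exhaustive = TRUE, n_used = 1L))
  n <- nA + nB
  n_assign <- choose(n, nA)
  exhaustive <- switch(method,
    auto = n_assign <= n_permutations,
    exhaustive = if (n_assign > 1e6)
      stop("too many assignments to enumerate: ", n_assign) else TRUE,
    montecarlo = FALSE)
  if (exhaustive) {
    cmb <- utils::combn(n, nA)
    if (statistic == "mean") {
      sA <- colSums(matrix(v[cmb], nrow = nA))
      stat <- sA / nA - (sum(v) - sA) / nB
    } else {
      stat <- apply(cmb, 2L, function(i) stats::median(v[i]) - stats::median(v[-i]))
    }
    n_used <- ncol(cmb)
  } else {
    if (statistic == "mean") {
      tot <- sum(v)
      stat <- vapply(seq_len(n_permutations), function(i) {
        sA <- sum(v[sample.int(n, nA)])
        sA / nA - (tot - sA) / nB
      }, 0)
    } else {
      stat <- vapply(seq_len(n_permutations), function(i) {
        idx <- sample.int(n, nA)
        stats::median(v[idx]) - stats::median(v[-idx])
      }, 0)
    }
    n_used <- n_permutations
  }
  eps <- 1e-8 * (abs(obs) + 1)
  cnt <- switch(sided,
    two = sum(abs(stat) >= abs(obs) - eps),
    greater = sum(stat >= obs - eps),
    less = sum(stat <= obs + eps))
  list(p = cnt / n_used, observed = obs, exhaustive = exhaustive, n_used = n_used)
}

#' Single-case effect size with averaged-SD denominator
#'
#' \deqn{d = |A - B| / ((sd_A + sd_B) / 2)}
#' where \eqn{A - B} is the phase mean (or median) difference and the
#' denominator is the unweighted average of the two phase sample standard
#' deviations. The classification for single-case effect sizes of this kind
#' is: small below 1.00, medium from 1.00 up to (excluding) 2.50, large from
#' 2.50.
#'
#' @param diff the phase difference (sign ignored).
#' @param sdA,sdB sample standard deviations of the phases.
#' @return The effect size in SD units.
#' @examples
#' effect_size(9.727, 4.052, 7.228)  # ~ 1.725
#' @export
effect_size <- function(diff, sdA, sdB) {
  if (is.na(sdA) || is.na(sdB)) return(NA_real_)
  if (sdA + sdB <= 0) stop("zero variability: effect size undefined")
  abs(diff) / ((sdA + sdB) / 2)
}

#' @rdname effect_size
#' @param d a non-negative effect size.
#' @export
classify_effect_size <- function(d) {
  if (is.na(d)) return(NA_character_)
  if (d < 0) stop("effect size must be non-negative")
  if (d < 1) "small" else if (d < 2.5) "medium" else "large"
}

subset_effect_size <- function(subset, statistic) {
  a <- subset$values[subset$phase == "A" & !is.na(subset$values)]
  b <- subset$values[subset$phase == "B" & !is.na(subset$values)]
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  d <- if (statistic == "mean") mean(a) - mean(b) else
    stats::median(a) - stats::median(b)
  sds <- stats::sd(a) + stats::sd(b)
  if (sds <= 0) return(NA_real_)
  abs(d) / (sds / 2)
}

#' Quadratic smoothing of the p-value course over k
#'
#' Fits a least-squares polynomial of degree `min(2, K - 1)` of the raw per-k
#' p-values on k and returns the predicted value at each k, clamped to
#' \eqn{[0, 1]}. With three or fewer distances the fit interpolates, so the
#' fitted values equal the raw ones.
#'
#' @param k integer distances.
#' @param raw_p raw per-k permutation p-values.
#' @return Fitted p-values, same length as `k`.
#' @export
fit_p_curve <- function(k, raw_p) {
  K <- length(k)
  stopifnot(length(raw_p) == K, K >= 1L)
  if (K <= 3L) return(pmin(pmax(raw_p, 0), 1))
  X <- cbind(1, k, k^2)
  fit <- stats::lm.fit(X, raw_p)
  pmin(pmax(as.numeric(X %*% fit$coefficients), 0), 1)
}

kmax_default <- function(n) max(1L, n %/% 10L)

#' Permutation distancing test
#'
#' Tests the null hypothesis that a single subject's outcomes have identical
#' distributions in phases A and B while controlling serial dependency by
#' stepwise down-sampling. For each temporal distance k = 1, 2, ... the
#' series is split into the k [build_subsets()]; each subset gets a
#' permutation p-value ([permutation_pvalue()]), an effect size and a
#' Ljung-Box diagnostic ([ljung_box()]). Per k these are aggregated (means of
#' p-values and effect sizes across subsets; dependency combined via
#' [combine_dependency()]). The procedure stops at the first distance where
#' the combined Ljung-Box p-value is at or above `alpha_lb` -- the favored k,
#' at which autocorrelation is no longer significantly present -- or at
#' `k_max`, with a warning flag, if the dependency never clears. The raw
#' p-value course is smoothed with [fit_p_curve()]; the headline p-value is
#' the fitted value at the favored k.
#'
#' Subsets in which a phase has no non-missing value are dropped from the
#' aggregation with a warning; subsets too short for a Ljung-Box test are
#' skipped in the dependency summary.
#'
#' @param series an [ab_series] (use [make_equidistant()] first on raw
#'   records). The series is assumed free of linear trends; see
#'   [inspect_trend()] and [detrend()].
#' @param statistic `"mean"` or `"median"` phase difference.
#' @param n_permutations permutations per subset; exhaustive enumeration is
#'   used whenever feasible (see [permutation_pvalue()]).
#' @param alpha_lb significance level of the Ljung-Box gate.
#' @param k_max `"auto"` (`max(1, floor(n/10))`, so every subset keeps about
#'   ten observations) or an integer.
#' @param sided `"two"` (default), `"greater"` (improvement means A above B,
#'   e.g. symptom decline after treatment) or `"less"`.
#' @param combine dependency combination rule, see [combine_dependency()].
#' @param aggregate `"mean"`: per-k p is the mean of per-subset p-values
#'   (default). `"pooled"`: one restricted permutation null per k, reshuffling
#'   within every subset simultaneously and evaluating the full-series
#'   statistic (Monte Carlo only).
#' @param seed optional integer; fixing it makes the result reproducible
#'   bit for bit.
#' @return An object of class `pdt`: a list with `rows` (one data frame row
#'   per tested k: dependency diagnostics, raw and fitted p, effect size),
#'   `favored_k`, `gate_cleared`, `observed_statistic`, `p.value` (fitted p
#'   at the favored k), `effect_size`, `effect_label`, and the configuration.
#' @examples
#' s <- make_equidistant(fitnet_plus())
#' pdt(s, sided = "greater", seed = 1)
#' @export
pdt <- function(series, statistic = c("mean", "median"),
                n_permutations = 10000L, alpha_lb = 0.05, k_max = "auto",
                sided = c("two", "greater", "less"),
                combine = c("min", "fisher"), aggregate = c("mean", "pooled"),
                seed = NULL) {
  stopifnot(inherits(series, "ab_series"))
  statistic <- match.arg(statistic)
  sided <- match.arg(sided)
  combine <- match.arg(combine)
  aggregate <- match.arg(aggregate)
  stopifnot(n_permutations >= 1, alpha_lb > 0, alpha_lb < 1)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  n <- nrow(series)
  k_max <- if (identical(k_max, "auto")) kmax_default(n) else as.integer(k_max)
  stopifnot(k_max >= 1L, k_max <= n)

  observed <- phase_diff(series$y, as.character(series$phase), statistic)
  rows <- vector("list", k_max)
  gate_cleared <- FALSE
  for (k in seq_len(k_max)) {
    rows[[k]] <- pdt_k_row(series, k, statistic, n_permutations, sided,
                           combine, aggregate)
    gp <- rows[[k]]$combined_p
    if (!is.na(gp) && gp >= alpha_lb) { gate_cleared <- TRUE; break }
    if (is.na(gp)) {
      warning("dependency diagnostics unavailable at k = ", k,
              "; distancing stopped")
      break
    }
  }
  rows <- do.call(rbind, Filter(Negate(is.null), rows))
  K <- nrow(rows)
  favored_k <- rows$k[K]
  if (!gate_cleared && K == k_max)
    warning("autocorrelation still significant at k_max = ", k_max,
            "; reporting k_max")
  rows$fitted_p <- fit_p_curve(rows$k, rows$raw_p)
  structure(list(
    rows = rows, favored_k = favored_k, gate_cleared = gate_cleared,
    observed_statistic = observed,
    p.value = rows$fitted_p[K],
    effect_size = rows$effect_size[K],
    effect_label = classify_effect_size(rows$effect_size[K]),
    statistic = statistic, sided = sided, n_permutations = n_permutations,
    alpha_lb = alpha_lb, k_max = k_max, combine = combine,
    aggregate = aggregate, seed = seed, n = n), class = "pdt")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# one row of the per-k table
pdt_k_row <- function(series, k, statistic, n_permutations, sided,
                      combine, aggregate) {
  subsets <- build_subsets(series, k)
  usable <- vapply(subsets, function(s) {
    keep <- !is.na(s$values)
    any(s$phase[keep] == "A") && any(s$phase[keep] == "B")
  }, TRUE)
  if (!any(usable)) stop("all subsets degenerate at k = ", k)
  if (!all(usable))
    warning(sum(!usable), " subset(s) with an empty phase dropped at k = ", k)
  subsets <- subsets[usable]

  lb <- lapply(subsets, function(s) {
    v <- s$values[!is.na(s$values)]
    if (length(v) < 3L || stats::var(v) == 0) NULL else ljung_box(v)
  })
  dep <- combine_dependency(lb, k, method = combine)

  es <- vapply(subsets, subset_effect_size, 0, statistic = statistic)

  if (aggregate == "mean") {
    ps <- vapply(subsets, function(s)
      permutation_pvalue(s$values, s$phase, statistic, n_permutations, sided)$p, 0)
    raw_p <- mean(ps)
  } else {
    raw_p <- pooled_permutation_p(subsets, statistic, n_permutations, sided)
  }
  data.frame(k = k, n_subsets = length(subsets), mean_r1 = dep$mean_r1,
             mean_Q = dep$mean_Q, combined_p = dep$combined_p,
             raw_p = raw_p, effect_size = mean(es, na.rm = TRUE))
}

# restricted permutation null: reshuffle within every subset simultaneously,
# statistic on the recombined full data
pooled_permutation_p <- function(subsets, statistic, n_permutations, sided) {
  parts <- lapply(subsets, function(s) {
    keep <- !is.na(s$values)
    list(v = s$values[keep], lab = s$phase[keep])
  })
  v_all <- unlist(lapply(parts, `[[`, "v"))
  lab_all <- unlist(lapply(parts, `[[`, "lab"))
  obs <- phase_diff(v_all, lab_all, statistic)
  stat <- vapply(seq_len(n_permutations), function(i) {
    labs <- unlist(lapply(parts, function(p) sample(p$lab)))
    phase_diff(v_all, labs, statistic)
  }, 0)
  eps <- 1e-8 * (abs(obs) + 1)
  cnt <- switch(sided,
    two = sum(abs(stat) >= abs(obs) - eps),
    greater = sum(stat >= obs - eps),
    less = sum(stat <= obs + eps))
  cnt / n_permutations
}

#' @export
print.pdt <- function(x, digits = 3, ...) {
  cat("Permutation distancing test\n")
  cat(sprintf("statistic: phase %s difference (A - B), %s-sided, %d permutations/subset\n",
              x$statistic, x$sided, x$n_permutations))
  tab <- x$rows
  out <- data.frame(k = tab$k, autocorrelation = round(tab$mean_r1, digits),
                    Q = round(tab$mean_Q, digits),
                    `LB p` = round(tab$combined_p, digits),
                    `raw p` = round(tab$raw_p, digits),
                    `fitted p` = round(tab$fitted_p, digits),
                    `effect size` = round(tab$effect_size, digits),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  cat(sprintf("favored k: %d%s\n", x$favored_k,
              if (x$gate_cleared) "" else " (autocorrelation not cleared; k_max reached)"))
  cat(sprintf("observed statistic: %.*f\n", digits, x$observed_statistic))
  cat(sprintf("p-value (fitted, favored k): %.*f\n", digits, x$p.value))
  cat(sprintf("effect size: %.*f (%s)\n", digits, x$effect_size, x$effect_label))
  invisible(x)
}

#' @export
as.data.frame.pdt <- function(x, ...) {
  df <- x$rows
  df$favored <- df$k == x$favored_k
  df$observed_statistic <- x$observed_statistic
  df
}
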