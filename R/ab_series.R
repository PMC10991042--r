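#' Single-case AB-phase series
#'
#' An `ab_series` is the data model used throughout the package: an
#' equidistant single-subject time series with a baseline phase (A) followed
#' by an intervention phase (B). It is a data frame with columns
#' `time` (strictly increasing consecutive integers), `phase` (factor with
#' levels `A`, `B`; all A records precede all B records) and `y` (numeric
#' outcome, `NA` allowed).
#'
#' Raw observational records rarely satisfy these invariants (missing weeks,
#' duplicated time markers); use [make_equidistant()] to repair them first.
#'
#' @param time integer time markers, consecutive and strictly increasing.
#' @param phase phase labels, `"A"` or `"B"` (character or factor).
#' @param y numeric outcomes; `NA` marks a missing observation.
#'
#' @return An object of class `ab_series` (also a `data.frame`).
#' @seealso [make_equidistant()], [phase_summary()], [plot_series()]
#' @examples
#' s <- ab_series(1:10, rep(c("A", "B"), each = 5), c(5, 6, 5, 7, 6, 3, 2, 4, 3, 2))
#' phase_summary(s)
#' @export
ab_series <- function(time, phase, y) {
  time <- as.integer(time)
  phase <- normalize_phase(phase)
  y <- as.numeric(y)
  n <- length(time)
  if (length(phase) != n || length(y) != n)
    stop("time, phase and y must have equal length")
  if (n < 2L) stop("an AB series needs at least two records")
  if (anyNA(time)) stop("time markers must be finite integers")
  validate_ab_series(data.frame(time = time, phase = phase, y = y))
}

validate_ab_series <- function(df) {
  if (any(diff(df$time) != 1L))
    stop("time markers must be consecutive integers (equidistant, step 1); ",
         "use make_equidistant() on raw records")
  ph <- as.character(df$phase)
  if (!all(ph %in% c("A", "B"))) stop("phase labels must be 'A' or 'B'")
  if (is.unsorted(match(ph, c("A", "B"))))
    stop("phase labels must be non-decreasing: all A records precede all B records")
  if (!any(ph == "A") || !any(ph == "B"))
    stop("both phases must be present")
  for (p in c("A", "B"))
    if (all(is.na(df$y[ph == p]))) stop("phase without observations: ", p)
  df$phase <- factor(ph, levels = c("A", "B"))
  rownames(df) <- NULL
  structure(df, class = c("ab_series", "data.frame"))
}

normalize_phase <- function(phase) {
  ph <- toupper(trimws(as.character(phase)))
  if (anyNA(ph) || !all(ph %in% c("A", "B")))
    stop("phase labels must be 'A' or 'B'")
  ph
}

#' Repair raw records into an equidistant AB series
#'
#' Distancing requires an equidistant series: every integer time marker
#' between the first and the last present exactly once. Raw single-case data
#' often violate this, so `make_equidistant()` applies two repairs, logging
#' each one:
#'
#' 1. *Missing time markers* are inserted with `NA` outcomes. An inserted
#'    marker inherits the phase of the block it falls in: markers before the
#'    first B-labelled record become A, later ones B (phases are contiguous
#'    by design).
#' 2. *Duplicate time markers* are resolved in this order: shift the first
#'    duplicate's outcome to the preceding marker if that slot is free
#'    (compensating an early observation); otherwise shift the last
#'    duplicate's outcome to the following marker if that slot is free
#'    (a delayed observation); otherwise replace the duplicates by their
#'    mean outcome.
#'
#' The function is idempotent: applied to its own output it is the identity.
#'
#' @param records a data frame with columns `time`, `phase` and `y`
#'   (see [read_ab_series()]), or an existing `ab_series`.
#' @return An [ab_series] whose `"preprocessing"` attribute is a character
#'   vector logging every mutation (empty if the input was already
#'   equidistant).
#' @examples
#' raw <- fitnet_plus()          # week 22 is absent
#' s <- make_equidistant(raw)
#' attr(s, "preprocessing")
#' @export
make_equidistant <- function(records) {
  df <- as.data.frame(records)
  if (!all(c("time", "phase", "y") %in% names(df)))
    stop("records must have columns time, phase, y")
  if (nrow(df) == 0L) stop("records must be non-empty")
  time <- as.integer(df$time)
  if (anyNA(time)) stop("time markers must be finite integers")
  phase <- normalize_phase(df$phase)
  y <- as.numeric(df$y)
  if (!any(phase == "A") || !any(phase == "B"))
    stop("at least one record per phase is required")

  ord <- order(time)
  time <- time[ord]; phase <- phase[ord]; y <- y[ord]
  log <- character(0)

  # phase of any marker, by contiguous-block rule
  first_b <- min(time[phase == "B"])
  if (any(phase == "A" & time >= first_b))
    stop("conflicting phase labels: A records at or after the first B marker")
  block_phase <- function(t) ifelse(t < first_b, "A", "B")

  # slot map over the full grid
  grid <- seq(min(time), max(time))
  slots <- vector("list", length(grid))
  for (i in seq_along(time)) {
    j <- time[i] - grid[1L] + 1L
    slots[[j]] <- c(slots[[j]], y[i])
    pj <- attr(slots[[j]], "phase")
    if (!is.null(pj) && pj != phase[i])
      stop("conflicting phase labels at time marker ", time[i])
    attr(slots[[j]], "phase") <- phase[i]
  }

  free <- function(j) j >= 1L && j <= length(slots) &&
    (is.null(slots[[j]]) || all(is.na(unclass(slots[[j]]))))

  for (j in seq_along(slots)) {
    while (length(slots[[j]]) > 1L) {
      t <- grid[j]
      vals <- unclass(slots[[j]])
      if (free(j - 1L)) {
        moved <- vals[1L]
        slots[[j]] <- structure(vals[-1L], phase = attr(slots[[j]], "phase"))
        slots[[j - 1L]] <- structure(moved, phase = block_phase(grid[j - 1L]))
        log <- c(log, sprintf(
          "duplicate marker %d: shifted first duplicate (y = %s) back to marker %d",
          t, format(moved), grid[j - 1L]))
      } else if (free(j + 1L)) {
        moved <- vals[length(vals)]
        slots[[j]] <- structure(vals[-length(vals)], phase = attr(slots[[j]], "phase"))
        slots[[j + 1L]] <- structure(moved, phase = block_phase(grid[j + 1L]))
        log <- c(log, sprintf(
          "duplicate marker %d: shifted last duplicate (y = %s) forward to marker %d",
          t, format(moved), grid[j + 1L]))
      } else {
        m <- mean(vals, na.rm = !all(is.na(vals)))
        slots[[j]] <- structure(m, phase = attr(slots[[j]], "phase"))
        log <- c(log, sprintf(
          "duplicate marker %d: mean-aggregated %d values to y = %s",
          t, length(vals), format(m)))
      }
    }
  }

  out_y <- vapply(slots, function(s) if (is.null(s)) NA_real_ else as.numeric(s)[1L], 0)
  inserted <- vapply(slots, is.null, TRUE)
  if (any(inserted))
    log <- c(log, sprintf("inserted missing time marker %d with NA outcome",
                          grid[inserted]))
  out <- validate_ab_series(data.frame(
    time = grid, phase = block_phase(grid), y = out_y))
  attr(out, "preprocessing") <- log
  out
}

#' Per-phase summary statistics
#'
#' Counts, means, medians and sample standard deviations (denominator
#' \eqn{n-1}) of the non-missing outcomes of each phase. When a phase has
#' fewer than two non-missing values its standard deviation is `NA`,
#' not zero.
#'
#' @param series an [ab_series].
#' @return A data frame with one row per phase and columns
#'   `phase`, `n`, `mean`, `median`, `sd`.
#' @examples
#' phase_summary(make_equidistant(fitnet_plus()))
#' @export
phase_summary <- function(series) {
  stopifnot(inherits(series, "ab_series"))
  out <- lapply(c("A", "B"), function(p) {
    v <- series$y[series$phase == p]
    v <- v[!is.na(v)]
    data.frame(phase = p, n = length(v), mean = mean(v), median = stats::median(v),
               sd = if (length(v) >= 2L) stats::sd(v) else NA_real_)
  })
  do.call(rbind, out)
}

#' Inspect linear trends per phase
#'
#' The distancing test assumes AB data without linear trends; this fits an
#' ordinary least-squares regression of the outcome on time within each phase
#' and reports the slope with its two-sided test p-value, for visual or formal
#' screening before testing.
#'
#' @param series an [ab_series].
#' @param phases which phases to inspect (default both).
#' @return A data frame with columns `phase`, `slope`, `se`, `p.value`, `n`.
#' @examples
#' inspect_trend(make_equidistant(fitnet_plus()))
#' @export
inspect_trend <- function(series, phases = c("A", "B")) {
  stopifnot(inherits(series, "ab_series"))
  phases <- match.arg(phases, c("A", "B"), several.ok = TRUE)
  out <- lapply(phases, function(p) {
    keep <- series$phase == p & !is.na(series$y)
    if (sum(keep) < 3L)
      stop("inspect_trend needs at least 3 non-missing values in phase ", p)
    fit <- stats::lm(y ~ time, data = series[keep, ])
    cf <- summary(fit)$coefficients
    data.frame(phase = p, slope = cf["time", 1L], se = cf["time", 2L],
               p.value = cf["time", 4L], n = sum(keep))
  })
  do.call(rbind, out)
}

#' Remove linear trends within phases
#'
#' Subtracts the within-phase ordinary least-squares trend from the selected
#' phases and adds the phase mean back, so phase means -- and with them the
#' observed mean-difference statistic -- are preserved exactly. Detrending is
#' deliberately not applied automatically anywhere in the package: removing a
#' trend can under- or overestimate the treatment effect and should be an
#' explicit analyst decision.
#'
#' @param series an [ab_series].
#' @param phases phases to detrend: `"A"`, `"B"` or both.
#' @return A detrended [ab_series].
#' @examples
#' s <- make_equidistant(fitnet_plus())
#' d <- detrend(s, phases = "B")
#' inspect_trend(d, "B")$slope   # ~ 0
#' @export
detrend <- function(series, phases = c("A", "B")) {
  stopifnot(inherits(series, "ab_series"))
  phases <- match.arg(phases, c("A", "B"), several.ok = TRUE)
  for (p in phases) {
    keep <- series$phase == p & !is.na(series$y)
    if (sum(keep) < 3L)
      stop("detrend needs at least 3 non-missing values in phase ", p)
    fit <- stats::lm(y ~ time, data = series[keep, ])
    series$y[keep] <- stats::residuals(fit) + mean(series$y[keep])
  }
  series
}

#' @export
as.data.frame.ab_series <- function(x, ...) {
  attr(x, "preprocessing") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.ab_series <- function(x, ...) {
  ns <- table(x$phase)
  miss <- sum(is.na(x$y))
  cat(sprintf(
    "AB-phase series: %d time markers (%d..%d), phase A %d, phase B %d, %d missing\n",
    nrow(x), min(x$time), max(x$time), ns[["A"]], ns[["B"]], miss))
  print.data.frame(x, ...)
  invisible(x)
}
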