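#' Read raw AB-phase records from a delimited text file
#'
#' Expects a header with (by default) columns `time`, `phase` and `y`;
#' empty fields and the tokens in `missing` mark missing outcomes. The
#' returned records are raw -- pass them through [make_equidistant()] before
#' testing.
#'
#' @param path file path.
#' @param time_col,phase_col,y_col column names to use.
#' @param missing character tokens that encode a missing outcome.
#' @param sep field separator.
#' @return A data frame with columns `time`, `phase`, `y`.
#' @examples
#' path <- system.file("extdata", "fitnet_plus.csv", package = "pdtest")
#' head(read_ab_series(path))
#' @export
read_ab_series <- function(path, time_col = "time", phase_col = "phase",
                           y_col = "y", missing = c("", "NA"), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", na.strings = missing,
                          strip.white = TRUE, check.names = FALSE)
  for (col in c(time_col, phase_col, y_col))
    if (!col %in% names(df)) stop("missing required column: ", col)
  parse_num <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      stop(sprintf("unparseable %s value '%s' in row %d", what, x[bad[1L]], bad[1L]))
    out
  }
  time <- parse_num(df[[time_col]], "time")
  if (anyNA(time) || any(time != round(time)))
    stop("time markers must be integers")
  data.frame(time = as.integer(time),
             phase = normalize_phase(df[[phase_col]]),
             y = parse_num(df[[y_col]], "outcome"))
}

#' Write an AB series (or raw records) to CSV
#'
#' Missing outcomes are written as `NA`, so [read_ab_series()] round-trips
#' the file.
#'
#' @param series an [ab_series] or a raw record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ab_series <- function(series, path) {
  df <- as.data.frame(series)[, c("time", "phase", "y")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' The packaged worked-example dataset
#'
#' Weekly fatigue severity (CIS-8 total score, range 8-56, higher = more
#' fatigued; validated severe-fatigue cut-off above 39) of one chronically
#' fatigued adolescent observed for 11 weeks before (phase A) and 26 weeks
#' after (phase B) the start of internet-delivered cognitive behavioural
#' therapy. Week 22 was not observed, so the raw records are not equidistant.
#'
#' @return A data frame of 37 raw records (columns `time`, `phase`, `y`);
#'   apply [make_equidistant()] to obtain the 38-marker analysis series.
#' @examples
#' s <- make_equidistant(fitnet_plus())
#' phase_summary(s)
#' @export
fitnet_plus <- function() {
  read_ab_series(system.file("extdata", "fitnet_plus.csv", package = "pdtest"))
}

#' Plot an AB series with phase level lines
#'
#' Phase A and B are drawn in distinct colors with a horizontal line at each
#' phase's mean (or median) over non-missing outcomes; optionally a clinical
#' cut-off line is added.
#'
#' @param series an [ab_series].
#' @param statistic `"mean"` or `"median"` level lines.
#' @param cutoff optional numeric: horizontal clinical cut-off.
#' @return A ggplot object.
#' @examples
#' plot_series(make_equidistant(fitnet_plus()), cutoff = 39)
#' @export
plot_series <- function(series, statistic = c("mean", "median"), cutoff = NULL) {
  stopifnot(inherits(series, "ab_series"))
  statistic <- match.arg(statistic)
  df <- as.data.frame(series)
  fun <- if (statistic == "mean") mean else stats::median
  levels_df <- do.call(rbind, lapply(c("A", "B"), function(p) {
    v <- df$y[df$phase == p]
    data.frame(phase = p, level = fun(v[!is.na(v)]),
               from = min(df$time[df$phase == p]),
               to = max(df$time[df$phase == p]))
  }))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$y,
                                         colour = .data$phase)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_segment(data = levels_df,
      ggplot2::aes(x = .data$from, xend = .data$to, y = .data$level,
                   yend = .data$level, colour = .data$phase),
      inherit.aes = FALSE, linewidth = 0.4) +
    ggplot2::labs(x = "time", y = "outcome",
                  subtitle = sprintf("horizontal lines: phase %ss", statistic)) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff))
    gg <- gg + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  gg
}

#' Preprocess and test an AB series in one call
#'
#' Convenience wrapper used by the command-line interface: repairs raw
#' records with [make_equidistant()], runs the requested tests, and bundles
#' everything -- input summary, preprocessing log, per-phase statistics,
#' results and the configuration -- into one report so each number is
#' regenerable.
#'
#' @param records raw records (data frame) or an [ab_series].
#' @param tests subset of `"pdt"`, `"scrt"`, `"traditional"`.
#' @param statistic,n_permutations,sided,seed passed to the tests
#'   ([pdt()]'s `sided` is also used for [perm_test()]; [scrt()] gets
#'   `"greater"` when `sided` is two-sided).
#' @param n1_min passed to [scrt()].
#' @return A list of class `ab_report`.
#' @examples
#' analyze(fitnet_plus(), tests = "pdt", sided = "greater",
#'         n_permutations = 500, seed = 1)
#' @export
analyze <- function(records, tests = c("pdt", "scrt", "traditional"),
                    statistic = c("mean", "median"), n_permutations = 10000L,
                    sided = c("two", "greater", "less"), n1_min = 1L,
                    seed = NULL) {
  tests <- match.arg(tests, several.ok = TRUE)
  statistic <- match.arg(statistic)
  sided <- match.arg(sided)
  series <- make_equidistant(records)
  results <- list()
  if ("pdt" %in% tests)
    results$pdt <- pdt(series, statistic = statistic,
                       n_permutations = n_permutations, sided = sided,
                       seed = seed)
  if ("scrt" %in% tests)
    results$scrt <- scrt(series, n1_min = n1_min, statistic = statistic,
                         sided = if (sided == "two") "greater" else sided)
  if ("traditional" %in% tests)
    results$traditional <- perm_test(series, statistic = statistic,
                                     n_permutations = n_permutations,
                                     sided = sided, seed = seed)
  structure(list(series = series,
                 preprocessing = attr(series, "preprocessing"),
                 phase_summary = phase_summary(series),
                 results = results,
                 config = list(tests = tests, statistic = statistic,
                               n_permutations = n_permutations, sided = sided,
                               n1_min = n1_min, seed = seed)),
            class = "ab_report")
}

#' @export
print.ab_report <- function(x, ...) {
  ns <- table(x$series$phase)
  cat(sprintf("AB-phase analysis: %d markers (A %d, B %d), %d missing\n",
              nrow(x$series), ns[["A"]], ns[["B"]], sum(is.na(x$series$y))))
  if (length(x$preprocessing)) {
    cat("preprocessing:\n")
    for (m in x$preprocessing) cat("  -", m, "\n")
  }
  print(x$phase_summary, row.names = FALSE)
  for (r in x$results) { cat("\n"); print(r) }
  invisible(x)
}
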