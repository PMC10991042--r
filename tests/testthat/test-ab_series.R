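test_that("missing time markers are inserted with NA and the block phase", {
  raw <- fitnet_plus()
  expect_false(22 %in% raw$time)
  s <- make_equidistant(raw)
  expect_equal(nrow(s), 38)
  expect_equal(s$time, -11:26)
  expect_true(is.na(s$y[s$time == 22]))
  expect_equal(as.character(s$phase[s$time == 22]), "B")
  expect_match(attr(s, "preprocessing"), "inserted missing time marker 22")
})

test_that("duplicate markers shift backward into a free slot first", {
  # duplicate week 23 (y 29 then 27), week 22 missing: 29 moves back to 22
  raw <- records(c(18:21, 23, 23, 24:26), rep("B", 9),
                 c(46, 42, 34, 27, 29, 27, 28, 21, 24))
  raw <- rbind(records(16:17, "A", c(40, 41)), raw)
  s <- make_equidistant(raw)
  expect_equal(s$y[s$time == 22], 29)
  expect_equal(s$y[s$time == 23], 27)
})

test_that("duplicates shift forward, then mean-aggregate, in that order", {
  # forward: marker 24 absent, so the last duplicate moves there
  raw <- records(c(1, 2, 3, 23, 23, 22, 21, 25), c("A", "A", "A", rep("B", 5)),
                 c(5, 6, 5, 29, 27, 30, 31, 33))
  s <- make_equidistant(raw)
  expect_equal(s$y[s$time == 23], 29)
  expect_equal(s$y[s$time == 24], 27)
  # both neighbors occupied: mean(29, 27) = 28
  raw2 <- records(c(1, 2, 3, 22, 23, 23, 24), c(rep("A", 3), rep("B", 4)),
                  c(5, 6, 5, 30, 29, 27, 31))
  s2 <- make_equidistant(raw2)
  expect_equal(s2$y[s2$time == 23], 28)
})

test_that("make_equidistant is idempotent and conserves observed values", {
  raw <- fitnet_plus()
  s1 <- make_equidistant(raw)
  s2 <- make_equidistant(s1)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_length(attr(s2, "preprocessing"), 0)
  expect_equal(sort(s1$y[!is.na(s1$y)]), sort(raw$y))
  expect_equal(nrow(s1), max(raw$time) - min(raw$time) + 1)
})

test_that("invalid inputs are rejected", {
  expect_error(make_equidistant(records(1:3, c("A", "A", "A"), 1:3)),
               "per phase")
  expect_error(make_equidistant(records(c(1, 2, 2, 3), c("A", "A", "B", "B"),
                                        c(1, 2, 3, 4))),
               "conflicting phase")
  expect_error(make_equidistant(records(1:4, c("A", "B", "A", "B"), 1:4)),
               "conflicting phase|first B")
  expect_error(ab_series(c(1, 3, 4), c("A", "B", "B"), 1:3), "consecutive")
  expect_error(ab_series(1:4, c("A", "B", "B", "B"), c(NA, 1, 2, 3)),
               "phase without observations")
})

test_that("phase_summary matches hand-computed statistics", {
  ps <- phase_summary(fitnet_series())
  expect_equal(ps$n, c(11, 26))
  expect_equal(ps$mean, c(492 / 11, 910 / 26))
  expect_equal(ps$sd, c(4.051936, 7.227724), tolerance = 1e-6)
  # invariant to inserting missing markers
  raw <- fitnet_plus()
  a <- raw[raw$phase == "A", ]; b <- raw[raw$phase == "B", ]
  expect_equal(ps$mean, c(mean(a$y), mean(b$y)))
  # constant series: sd 0, means equal
  cs <- phase_summary(toy_series(rep(3, 4), rep(3, 5)))
  expect_equal(cs$mean, c(3, 3))
  expect_equal(cs$sd, c(0, 0))
  # a phase with <2 observations reports NA sd, not zero
  one <- phase_summary(ab_series(1:4, c("A", "B", "B", "B"), c(5, 1, 2, 3)))
  expect_true(is.na(one$sd[1]))
})

test_that("trend inspection recovers known slopes", {
  t <- 1:20
  s <- ab_series(t, rep(c("A", "B"), each = 10), 2 * t)
  tr <- suppressWarnings(inspect_trend(s))  # exact fit warns
  expect_equal(tr$slope, c(2, 2), tolerance = 1e-10)
  # white noise slope ~ 0, p large on average
  set.seed(42)
  wn <- ab_series(1:200, rep(c("A", "B"), each = 100), rnorm(200))
  expect_lt(abs(inspect_trend(wn, "A")$slope), 0.02)
  # worked example phase A is trend-free
  expect_gt(inspect_trend(fitnet_series(), "A")$p.value, 0.05)
  expect_error(inspect_trend(ab_series(1:5, c("A", "A", "B", "B", "B"),
                                       c(1, 2, 3, 4, 5)), "A"),
               "at least 3")
})

test_that("detrend removes the slope but preserves phase means", {
  set.seed(7)
  t <- 1:30
  y <- ifelse(t <= 15, 10 + 0.5 * t, 20 - 0.3 * t) + rnorm(30, sd = 0.2)
  s <- ab_series(t, rep(c("A", "B"), each = 15), y)
  before <- phase_summary(s)$mean
  d <- detrend(s)
  expect_equal(phase_summary(d)$mean, before, tolerance = 1e-10)
  expect_equal(inspect_trend(d)$slope, c(0, 0), tolerance = 1e-10)
  # detrending a zero-slope (palindromic) phase changes nothing
  flat <- ab_series(1:20, rep(c("A", "B"), each = 10),
                    c(1, 2, 3, 2, 1, 1, 2, 3, 2, 1, rnorm(10)))
  expect_equal(detrend(flat, "A")$y, flat$y, tolerance = 1e-10)
})
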