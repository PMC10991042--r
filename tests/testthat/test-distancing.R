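test_that("distanced subsets start globally and partition the series", {
  s <- fitnet_series()
  subs <- build_subsets(s, 3)
  expect_length(subs, 3)
  # published example: at k = 3 the first subset's retained outcomes start
  # 48, 43, 44, 47 (every third week from the series start)
  expect_equal(subs[[1]]$values[1:4], c(48, 43, 44, 47))
  expect_equal(subs[[2]]$values[1:3], c(43, 42, 46))
  expect_equal(diff(subs[[1]]$positions), rep(3, 12))
  # partition property over several k
  for (k in c(1, 2, 3, 5, 7)) {
    subs <- build_subsets(s, k)
    expect_equal(sort(unlist(lapply(subs, `[[`, "positions"))), s$time)
    expect_equal(sort(unlist(lapply(subs, `[[`, "values")), na.last = TRUE),
                 sort(s$y, na.last = TRUE))
  }
  # k = 1 is the original series
  one <- build_subsets(s, 1)
  expect_length(one, 1)
  expect_equal(one[[1]]$values, s$y)
})

test_that("subset statistic is the phase difference on non-missing values", {
  s <- fitnet_series()
  expect_equal(subset_statistic(build_subsets(s, 1)[[1]]), 492 / 11 - 35)
  expect_equal(subset_statistic(list(values = c(1, 3, 2), phase = c("A", "A", "B")),
                                "mean"), 0)
  expect_true(is.na(subset_statistic(list(values = c(NA, 1), phase = c("A", "B")),
                                     "mean")))
})

test_that("exhaustive permutation p matches brute-force enumeration", {
  res <- permutation_pvalue(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
  expect_true(res$exhaustive)
  expect_equal(res$n_used, 20)
  expect_equal(res$p, 0.1)
  expect_equal(res$p, brute_perm_p(1:3, 4:6))
  # one-sided agrees with brute force too
  for (sd_ in c("greater", "less"))
    expect_equal(permutation_pvalue(c(1, 2, 3, 4, 5, 6),
                                    rep(c("A", "B"), each = 3),
                                    sided = sd_)$p,
                 brute_perm_p(1:3, 4:6, sd_))
  # median statistic
  expect_equal(permutation_pvalue(c(1, 2, 3, 9, 10, 11),
                                  rep(c("A", "B"), each = 3),
                                  statistic = "median")$p,
               brute_perm_p(1:3, 9:11, statistic = median))
  # symmetric data: observed 0 is the least extreme value
  expect_equal(permutation_pvalue(c(1, 2, 1, 2), c("A", "A", "B", "B"))$p, 1)
  # degenerate data
  expect_equal(permutation_pvalue(rep(4, 6), rep(c("A", "B"), each = 3))$p, 1)
})

test_that("Monte Carlo p converges to the exhaustive p (binomial bound)", {
  set.seed(5)
  cases <- list(list(a = c(3, 1, 4, 1), b = c(5, 9, 2, 6, 5)),
                list(a = c(2.3, 0.1, 1.7), b = c(4.1, 3.3, 2.2, 5.0)),
                list(a = rnorm(5), b = rnorm(5) + 1))
  nperm <- 10000
  for (cs in cases) {
    v <- c(cs$a, cs$b)
    lab <- rep(c("A", "B"), c(length(cs$a), length(cs$b)))
    p_ex <- permutation_pvalue(v, lab, method = "exhaustive")$p
    p_mc <- permutation_pvalue(v, lab, n_permutations = nperm,
                               method = "montecarlo")
    expect_false(p_mc$exhaustive)
    bound <- 2.576 * sqrt(p_ex * (1 - p_ex) / nperm) + 1e-3
    expect_lt(abs(p_mc$p - p_ex), bound)
  }
})

test_that("effect size uses the averaged-SD denominator and classifies correctly", {
  expect_equal(effect_size(9.727273, 4.051936, 7.227724), 1.724746,
               tolerance = 1e-6)
  expect_equal(effect_size(0, 1, 2), 0)
  # shift and positive scale invariance on real data
  s <- fitnet_series()
  ps <- phase_summary(s)
  d0 <- effect_size(diff(rev(ps$mean)), ps$sd[1], ps$sd[2])
  for (trans in list(function(y) y + 100, function(y) y * 3.7)) {
    s2 <- s; s2$y <- trans(s2$y)
    p2 <- phase_summary(s2)
    expect_equal(effect_size(p2$mean[1] - p2$mean[2], p2$sd[1], p2$sd[2]), d0,
                 tolerance = 1e-12)
  }
  expect_error(effect_size(1, 0, 0), "zero variability")
  expect_equal(classify_effect_size(0.99), "small")
  expect_equal(classify_effect_size(1.00), "medium")
  expect_equal(classify_effect_size(1.691), "medium")
  expect_equal(classify_effect_size(2.50), "large")
  expect_error(classify_effect_size(-0.1), "non-negative")
})

test_that("p-curve fitting interpolates for K <= 3 and least-squares beyond", {
  expect_equal(fit_p_curve(1, 0.4), 0.4)
  expect_equal(fit_p_curve(1:3, c(0, 0.006, 0.026)), c(0, 0.006, 0.026))
  # K = 5: compare against normal equations solved independently
  k <- 1:5
  p <- c(0, 0, 0, 0.5, 0)
  X <- cbind(1, k, k^2)
  beta <- solve(t(X) %*% X, t(X) %*% p)
  expect_equal(fit_p_curve(k, p), pmin(pmax(as.numeric(X %*% beta), 0), 1),
               tolerance = 1e-10)
  expect_true(all(fit_p_curve(k, p) >= 0 & fit_p_curve(k, p) <= 1))
})

test_that("the favored k is the first distance clearing the Ljung-Box gate", {
  # worked example: gate clears at k = 3
  r <- pdt(fitnet_series(), n_permutations = 2000, sided = "greater", seed = 1)
  expect_equal(r$favored_k, 3)
  expect_true(r$gate_cleared)
  expect_equal(nrow(r$rows), 3)
  # white noise: gate clears immediately at k = 1
  set.seed(8)
  wn <- ab_series(1:40, rep(c("A", "B"), each = 20), rnorm(40))
  expect_equal(pdt(wn, n_permutations = 500, seed = 1)$favored_k, 1)
  # a slow cycle stays autocorrelated at every feasible distance:
  # k_max is reached with a warning
  set.seed(9)
  t <- 1:40
  sar <- ab_series(t, rep(c("A", "B"), each = 20),
                   10 * sin(2 * pi * t / 40) + rnorm(40, sd = 0.1))
  expect_warning(rk <- pdt(sar, n_permutations = 200, seed = 1),
                 "k_max")
  expect_equal(rk$favored_k, rk$k_max)
  expect_false(rk$gate_cleared)
})

test_that("pdt results are reproducible and symmetric under phase reversal", {
  s <- fitnet_series()
  r1 <- pdt(s, n_permutations = 1000, seed = 42)
  r2 <- pdt(s, n_permutations = 1000, seed = 42)
  expect_identical(r1, r2)
  # swapping which values are A and which are B negates the statistic and
  # keeps the two-sided p (exhaustive enumeration; small series)
  a <- c(5, 6, 7, 5, 6); b <- c(3, 2, 4, 3, 2, 3)
  s1 <- toy_series(a, b)
  s2 <- toy_series(b, a)
  p1 <- suppressWarnings(pdt(s1, k_max = 1, n_permutations = 5000, seed = 1))
  p2 <- suppressWarnings(pdt(s2, k_max = 1, n_permutations = 5000, seed = 1))
  expect_equal(p1$observed_statistic, -p2$observed_statistic)
  expect_equal(p1$p.value, p2$p.value)
  # observed statistic does not depend on k_max
  expect_equal(suppressWarnings(pdt(s, k_max = 2, n_permutations = 100,
                                    seed = 1))$observed_statistic,
               r1$observed_statistic)
})

test_that("per-k aggregation averages subsets; pooled variant is available", {
  s <- fitnet_series()
  r <- pdt(s, n_permutations = 5000, sided = "greater", seed = 3)
  # k = 1 row: raw p equals the single-subset permutation p (same seed)
  one <- suppressWarnings(pdt(s, k_max = 1, n_permutations = 5000,
                              sided = "greater", seed = 3))
  expect_equal(one$rows$raw_p[1], r$rows$raw_p[1])
  expect_equal(one$rows$n_subsets, 1)
  # effect sizes per k are means of per-subset effect sizes
  es3 <- sapply(build_subsets(s, 3), function(sub) {
    a <- sub$values[sub$phase == "A" & !is.na(sub$values)]
    b <- sub$values[sub$phase == "B" & !is.na(sub$values)]
    abs(mean(a) - mean(b)) / ((sd(a) + sd(b)) / 2)
  })
  expect_equal(r$rows$effect_size[3], mean(es3), tolerance = 1e-12)
  # pooled restricted permutation returns a valid, much smaller p here
  rp <- pdt(s, n_permutations = 2000, sided = "greater",
            aggregate = "pooled", seed = 3)
  expect_true(all(rp$rows$raw_p >= 0 & rp$rows$raw_p <= 1))
  expect_lt(rp$rows$raw_p[3], r$rows$raw_p[3])
})
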