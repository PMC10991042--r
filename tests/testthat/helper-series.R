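# worked-example series, repaired once per test run
fitnet_series <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- make_equidistant(fitnet_plus())
    s
  }
})

# quick raw-record builder
records <- function(time, phase, y) data.frame(time = time, phase = phase, y = y)

# small two-phase series without fuss
toy_series <- function(a, b) ab_series(seq_len(length(a) + length(b)),
                                       rep(c("A", "B"), c(length(a), length(b))),
                                       c(a, b))

# brute-force two-group exhaustive permutation p, independent of the package
brute_perm_p <- function(a, b, sided = "two", statistic = mean) {
  v <- c(a, b); nA <- length(a); n <- length(v)
  obs <- statistic(a) - statistic(b)
  cmb <- combn(n, nA)
  s <- apply(cmb, 2, function(i) statistic(v[i]) - statistic(v[-i]))
  eps <- 1e-9
  switch(sided,
         two = mean(abs(s) >= abs(obs) - eps),
         greater = mean(s >= obs - eps),
         less = mean(s <= obs + eps))
}
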