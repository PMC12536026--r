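test_that("cross_correlate matches closed-form sinusoid geometry and basic identities", {
  t <- seq(0, by = 2, length.out = 230)
  g <- glym_ts(sin(2 * pi * t / 16), tr = 2)
  c <- glym_ts(-cos(2 * pi * t / 16), tr = 2)
  cc <- cross_correlate(g, c, max_lag = 10)
  expect_equal(cc$lag, seq(-10, 10, by = 2))
  # g advanced by +4 s is cos, so r(+4) = cor(cos, -cos) = -1 exactly
  expect_equal(cc$r[cc$lag == 4], -1, tolerance = 1e-8)
  expect_equal(cc$r[cc$lag == -4], 1, tolerance = 1e-8)
  # identical series: r(0) = 1 and it is the global maximum
  self <- cross_correlate(g, g, max_lag = 10)
  expect_equal(self$r[self$lag == 0], 1)
  expect_equal(which.max(self$r), which(self$lag == 0))
  # r(0) equals the plain Pearson correlation of the full series
  set.seed(1)
  x <- glym_ts(rnorm(100), tr = 2); y <- glym_ts(rnorm(100), tr = 2)
  cc2 <- cross_correlate(x, y, max_lag = 8)
  expect_equal(cc2$r[cc2$lag == 0], cor(x$values, y$values))
  expect_true(all(abs(cc2$r) <= 1))
  # errors
  expect_error(cross_correlate(x, glym_ts(rnorm(90), tr = 2), 8), "length")
  expect_error(cross_correlate(x, glym_ts(rnorm(100), tr = 1), 8), "interval")
  expect_error(cross_correlate(x, y, max_lag = 3), "multiple")
})

test_that("lag-resolved r equals brute-force shifted Pearson at every grid lag", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(32:40, 1)
    g <- glym_ts(rnorm(n), tr = 2)
    c <- glym_ts(rnorm(n), tr = 2)
    k_max <- (n - 4) %/% 2
    max_lag <- min(k_max, 12) * 2
    cc <- cross_correlate(g, c, max_lag = max_lag)
    for (i in seq_len(nrow(cc))) {
      k <- as.integer(round(cc$lag[i] / 2))
      expect_equal(cc$r[i], brute_lag_pearson(g$values, c$values, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("lag reversal swaps the roles of the two series", {
  set.seed(15)
  a <- glym_ts(rnorm(80), tr = 2)
  b <- glym_ts(rnorm(80), tr = 2)
  ab <- cross_correlate(a, b, max_lag = 10)
  ba <- cross_correlate(b, a, max_lag = 10)
  expect_equal(ab$r, rev(ba$r), tolerance = 1e-12)
})

test_that("independent white-noise pairs stay inside the null band", {
  set.seed(23)
  g <- glym_ts(rnorm(230), tr = 2)
  c <- glym_ts(rnorm(230), tr = 2)
  cc <- cross_correlate(g, c, max_lag = 10)
  expect_true(all(abs(cc$r) < 4 / sqrt(230)))
})

test_that("coupling_index is the signed negation of r at the index lag", {
  cc <- structure(data.frame(lag = seq(-10, 10, 2),
                             r = c(rep(0, 6), 0.3, -0.16, 0, 0.05, 0)),
                  class = c("cross_correlogram", "data.frame"), tr = 2)
  expect_equal(coupling_index(cc), 0.16)           # anticorrelation -> positive
  expect_equal(coupling_index(cc, index_lag = 6), 0)
  expect_equal(coupling_index(cc, index_lag = 8), -0.05)  # sign convention
  expect_error(coupling_index(cc, index_lag = 3), "grid")
})

test_that("derivative_coupling tracks the coupling strength", {
  p1 <- generate_signal_pair(signal_config(coupling_strength = 1, seed = 4))
  expect_equal(derivative_coupling(p1$gbold, p1$csf), 1, tolerance = 1e-10)
  p0 <- generate_signal_pair(signal_config(coupling_strength = 0, seed = 4))
  expect_lt(abs(derivative_coupling(p0$gbold, p0$csf)), 4 / sqrt(240))
  # Monte-Carlo means increase monotonically in s
  set.seed(55)
  means <- vapply(c(0.2, 0.5, 0.8), function(s) {
    mean(vapply(sample.int(2^31 - 1, 40), function(sd_) {
      p <- generate_signal_pair(
        signal_config(n_volumes = 100, coupling_strength = s, seed = sd_))
      derivative_coupling(p$gbold, p$csf)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("group_mean_correlogram averages per lag and checks grids", {
  t <- seq(0, by = 2, length.out = 64)
  g <- glym_ts(rnorm(64), tr = 2); c <- glym_ts(rnorm(64), tr = 2)
  cc <- cross_correlate(g, c, max_lag = 8)
  expect_equal(group_mean_correlogram(list(cc))$r, cc$r)
  flipped <- cc; flipped$r <- -flipped$r
  expect_equal(group_mean_correlogram(list(cc, flipped))$r,
               rep(0, nrow(cc)))
  other <- cross_correlate(g, c, max_lag = 6)
  expect_error(group_mean_correlogram(list(cc, other)), "grid")
})

test_that("derivative-coupled cohorts put the negative extremum at +4 s", {
  pairs <- sim_coupled_cohort(20, 0.9, seed = 61, n_volumes = 240)
  cp <- cohort_coupling(pairs)
  gm <- group_mean_correlogram(cp$correlograms)
  expect_equal(gm$lag[which.min(gm$r)], 4)
  expect_equal(gm$lag[which.max(gm$r)], -4)
})

test_that("permutation test flags a coupled cohort and never returns p = 0", {
  pairs <- sim_coupled_cohort(20, 0.9, seed = 87)
  prepped <- lapply(pairs, function(p)
    list(gbold = prep_signal(p$gbold), csf = prep_signal(p$csf)))
  pt <- permutation_test(prepped, max_lag = 10, n_perm = 999, seed = 5)
  expect_equal(pt$p[pt$lags == 4], 1 / 1000)   # add-one floor, not zero
  expect_true(all(pt$p >= 1 / 1000 & pt$p <= 1))
  expect_true(all(pt$band95[1, ] <= pt$band95[2, ]))
  # p-values from different seeds agree to O(1/sqrt(n_perm))
  pt2 <- permutation_test(prepped, max_lag = 10, n_perm = 999, seed = 6)
  expect_lt(max(abs(pt$p - pt2$p)), 6 / sqrt(999))
  expect_error(permutation_test(prepped, n_perm = 0), "n_perm")
  expect_error(permutation_test(prepped[1:2], n_perm = 10), "3 subjects")
})

test_that("permutation test holds its type-I error and gains power with coupling", {
  set.seed(101)
  seeds <- sample.int(2^31 - 1, 200)
  reject_null <- vapply(seeds, function(s) {
    pairs <- sim_coupled_cohort(8, 0, seed = s, n_volumes = 64)
    prepped <- lapply(pairs, function(p)
      list(gbold = prep_signal(p$gbold, n_discard = 4),
           csf = prep_signal(p$csf, n_discard = 4)))
    pt <- permutation_test(prepped, max_lag = 4, n_perm = 199, seed = s)
    pt$p[pt$lags == 4] <= 0.05
  }, logical(1))
  rate <- mean(reject_null)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_gt(rate, 0.05 - 3 * se)
  expect_lt(rate, 0.05 + 3 * se)
  # monotone power in coupling strength at +4 s
  set.seed(202)
  sweep_seeds <- sample.int(2^31 - 1, 25)
  rates <- vapply(c(0, 0.4, 0.8), function(s) {
    mean(vapply(sweep_seeds, function(sd_) {
      pairs <- sim_coupled_cohort(8, s, seed = sd_, n_volumes = 64)
      prepped <- lapply(pairs, function(p)
        list(gbold = prep_signal(p$gbold, n_discard = 4),
             csf = prep_signal(p$csf, n_discard = 4)))
      pt <- permutation_test(prepped, max_lag = 4, n_perm = 99, seed = sd_)
      pt$p[pt$lags == 4] <= 0.05
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[3], 1)
})
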