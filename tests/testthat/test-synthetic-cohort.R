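test_that("identical config and seed reproduce marker tables and signals bit for bit", {
  a <- generate_marker_table(cohort_config(seed = 77))
  b <- generate_marker_table(cohort_config(seed = 77))
  attr(a, "config") <- attr(b, "config") <- NULL
  expect_identical(a, b)
  pa <- generate_signal_pair(signal_config(seed = 5))
  pb <- generate_signal_pair(signal_config(seed = 5))
  expect_identical(pa$gbold$values, pb$gbold$values)
  expect_identical(pa$csf$values, pb$csf$values)
})

test_that("marker table matches its configured structure", {
  cfg <- cohort_config(seed = 21)
  tab <- generate_marker_table(cfg)
  expect_equal(nrow(tab), cfg$n_als + cfg$n_hc)
  expect_equal(sum(tab$group == "ALS"), cfg$n_als)
  expect_false(anyDuplicated(tab$subject_id) > 0)
  # CPV fraction identity holds exactly per subject
  expect_equal(tab$cpv_fraction_pct, 100 * tab$cpv_ml / tab$tiv_ml,
               tolerance = 1e-12)
  # progression rate consistent with its formula
  als <- tab[tab$group == "ALS", ]
  expect_equal(als$progression_rate,
               (48 - als$alsfrs_r) / als$duration_months, tolerance = 1e-12)
  expect_true(all(als$alsfrs_r >= 0 & als$alsfrs_r <= 48))
  expect_true(all(als$duration_months > 0))
  # HC ALPS sample mean within 3 SE of its configured mean
  hc <- tab[tab$group == "HC", ]
  expect_lt(abs(mean(hc$alps_index) - 1.36), 3 * 0.14 / sqrt(nrow(hc)))
  expect_error(cohort_config(als_correlation = -1), "magnitude")
  expect_error(cohort_config(n_als = 1), "at least 2")
})

test_that("marker moments converge to the configured values at large n", {
  n <- 10000
  tab <- generate_marker_table(cohort_config(n_als = n, n_hc = n, seed = 3))
  als <- tab[tab$group == "ALS", ]
  hc <- tab[tab$group == "HC", ]
  expect_lt(abs(mean(als$alps_index) - 1.20), 4 * 0.16 / sqrt(n))
  expect_lt(abs(sd(als$alps_index) - 0.16), 0.005)
  expect_lt(abs(mean(als$coupling_index) - 0.01), 4 * 0.13 / sqrt(n))
  expect_lt(abs(mean(hc$coupling_index) - 0.16), 4 * 0.14 / sqrt(n))
  expect_lt(abs(mean(als$cpv_fraction_pct) - 0.09), 4 * 0.03 / sqrt(n))
  expect_lt(abs(median(hc$cpv_fraction_pct) - 0.06), 0.002)
})

test_that("the copula imposes (or removes) the ALPS-CPVfraction correlation", {
  # independence case at large n
  tab0 <- generate_marker_table(
    cohort_config(n_als = 10000, n_hc = 2, als_correlation = 0, seed = 9))
  als0 <- tab0[tab0$group == "ALS", ]
  expect_lt(abs(cor(als0$alps_index, als0$cpv_fraction_pct)), 3 / sqrt(10000))
  # imposed correlation recovered within the Fisher-z 95% CI in >= 90% of draws
  set.seed(31)
  seeds <- sample.int(2^31 - 1, 150)
  covered <- vapply(seeds, function(s) {
    tab <- generate_marker_table(cohort_config(seed = s))
    als <- tab[tab$group == "ALS", ]
    r <- cor(als$alps_index, als$cpv_fraction_pct)
    z <- atanh(r); half <- 1.96 / sqrt(nrow(als) - 3)
    ci <- tanh(c(z - half, z + half))
    ci[1] <= -0.537 && -0.537 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("signal pairs realize the derivative-coupling model", {
  # full coupling, no rectification: CSF equals the negated unit derivative
  p1 <- generate_signal_pair(signal_config(coupling_strength = 1, seed = 2))
  d <- temporal_derivative(p1$gbold)$values
  expect_equal(cor(-d, p1$csf$values), 1, tolerance = 1e-10)
  # zero coupling: every lag inside the white-noise null band
  p0 <- generate_signal_pair(signal_config(coupling_strength = 0, seed = 12))
  cc <- cross_correlate(p0$gbold, p0$csf, max_lag = 10)
  expect_true(all(abs(cc$r) < 4 / sqrt(240)))
  # spectral mass outside the passband is (numerically) zero
  g <- generate_signal_pair(signal_config(seed = 6))$gbold
  spec <- Mod(fft(g$values))^2
  freqs <- (seq_along(spec) - 1) / (length(spec) * g$tr)
  freqs <- pmin(freqs, 1 / g$tr - freqs)
  outside <- freqs < 0.01 | freqs > 0.1
  expect_lt(sum(spec[outside]) / sum(spec), 0.05)
  expect_error(signal_config(dominant_freq = 0.2), "Nyquist|dominant")
  # rectification clips the negative half-wave
  pr <- generate_signal_pair(signal_config(rectify_csf = TRUE, seed = 2))
  expect_gte(min(pr$csf$values), 0)
})

test_that("downstream coupling index is positive on average under strong coupling", {
  set.seed(40)
  idx <- vapply(sample.int(2^31 - 1, 60), function(s) {
    p <- generate_signal_pair(
      signal_config(n_volumes = 120, coupling_strength = 0.8, seed = s))
    coupling_index(cross_correlate(prep_signal(p$gbold),
                                   prep_signal(p$csf), max_lag = 10))
  }, numeric(1))
  expect_gt(mean(idx), 0)
  expect_gt(mean(idx > 0), 0.9)
})

test_that("phantom embedding recovers the injected series at the expected noise level", {
  pair <- generate_signal_pair(signal_config(n_volumes = 60, seed = 14))
  # noiseless: exact recovery of both series
  ph0 <- generate_phantom(pair, noise_sd = 0, seed = 3)
  expect_equal(extract_mask_mean(ph0$image4d, ph0$gm_mask, tr = 2)$values,
               pair$gbold$values, tolerance = 1e-12)
  expect_equal(extract_mask_mean(ph0$image4d, ph0$csf_mask, tr = 2)$values,
               pair$csf$values, tolerance = 1e-12)
  # noisy: residual sd ~ noise_sd / sqrt(k)
  ph <- generate_phantom(pair, grid_shape = c(10, 10, 4), noise_sd = 0.5,
                         seed = 4)
  k <- sum(ph$gm_mask)
  resid <- extract_mask_mean(ph$image4d, ph$gm_mask, tr = 2)$values -
    pair$gbold$values
  expect_lt(abs(sd(resid) - 0.5 / sqrt(k)), 0.4 * 0.5 / sqrt(k))
  # invalid masks
  full <- array(TRUE, c(6, 6, 4))
  expect_error(generate_phantom(pair, gm_mask = full, csf_mask = full),
               "overlap")
  empty <- array(FALSE, c(6, 6, 4))
  expect_error(generate_phantom(pair, gm_mask = empty), "nonempty")
})
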