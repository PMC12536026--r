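test_that("roc_analysis agrees with brute-force pair counting, ties included", {
  # hand cases
  expect_equal(roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1),
                            direction = "greater")$auc, 1.0)
  expect_equal(roc_analysis(c(1, 3, 2, 4), c(0, 0, 1, 1),
                            direction = "greater")$auc, 0.75)
  # perfectly separated: AUC 1 with perfect operating point
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))
  expect_equal(r$auc, 1.0)
  expect_equal(r$sens_at_cutoff, 1)
  expect_equal(r$spec_at_cutoff, 1)
  # random instances with ties, n <= 50
  set.seed(33)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(rnorm(n, mean = y), 1)  # rounding induces ties
    expect_equal(roc_analysis(s, y, direction = "greater")$auc,
                 brute_auc(s, y), tolerance = 1e-12)
  }
  expect_error(roc_analysis(rnorm(5), rep(1, 5)), "class")
})

test_that("AUC is invariant under monotone transforms and direction handles orientation", {
  set.seed(44)
  y <- rep(c(0, 1), each = 30)
  s <- rnorm(60, mean = y)
  a <- roc_analysis(s, y, direction = "greater")$auc
  expect_equal(roc_analysis(exp(s), y, direction = "greater")$auc, a)
  expect_equal(roc_analysis(plogis(3 * s), y, direction = "greater")$auc, a)
  # lower-is-positive markers orient to the same AUC
  expect_equal(roc_analysis(-s, y, direction = "less")$auc, a)
  expect_gte(roc_analysis(-s, y, direction = "auto")$auc, 0.5)
  # a single-feature logistic model has the same AUC as the raw feature
  fit <- fit_logistic(data.frame(x = s), y)
  expect_equal(roc_analysis(fit$fitted, y, direction = "greater")$auc, a)
})

test_that("DeLong interval brackets the point estimate and tightens with n", {
  widths <- vapply(c(50, 500), function(n) {
    set.seed(n)
    y <- rep(c(0, 1), each = n / 2)
    s <- rnorm(n, mean = 0.8 * y)
    r <- roc_analysis(s, y)
    expect_gte(r$auc, r$ci95[1])
    expect_lte(r$auc, r$ci95[2])
    r$ci95[2] - r$ci95[1]
  }, numeric(1))
  expect_lt(widths[2], widths[1] / 2)
})

test_that("mean empirical AUC matches the closed-form binormal value", {
  set.seed(52)
  auc <- replicate(100, {
    x <- rnorm(41, 0.01, 0.13); y <- rnorm(43, 0.16, 0.14)
    roc_analysis(c(x, y), rep(c(1, 0), c(41, 43)), direction = "less")$auc
  })
  expect_equal(mean(auc), binormal_auc(0.16, 0.14, 0.01, 0.13),
               tolerance = 0.02)
})

test_that("fit_logistic recovers known coefficients and detects degeneracy", {
  set.seed(60)
  # null feature: slope ~ 0, intercept ~ logit(prevalence)
  x0 <- rnorm(4000)
  y0 <- rbinom(4000, 1, 0.3)
  f0 <- fit_logistic(data.frame(x = x0), y0)
  expect_equal(unname(f0$coefficients), 0, tolerance = 0.1)
  expect_equal(f0$intercept, qlogis(mean(y0)), tolerance = 0.15)
  # parameter recovery within 3 asymptotic SEs at n = 5000
  n <- 5000
  x <- rnorm(n)
  beta <- c(-1, 2)
  y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x))
  fit <- fit_logistic(data.frame(x = x), y)
  se <- logistic_se(cbind(1, x), beta)
  expect_lt(abs(fit$intercept - beta[1]), 3 * se[1])
  expect_lt(abs(unname(fit$coefficients) - beta[2]), 3 * se[2])
  expect_true(fit$converged)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  # complete separation is an error, not a divergent fit
  xs <- c(rnorm(20, -5), rnorm(20, 5))
  ys <- rep(c(0, 1), each = 20)
  expect_error(fit_logistic(data.frame(x = xs), ys), "separation")
  # rank deficiency is an error
  expect_error(fit_logistic(data.frame(a = x, b = 2 * x), y), "rank")
  expect_error(fit_logistic(data.frame(x = 1:2), c(0, 1)), "observations")
})

test_that("nomogram point scales reproduce the model probabilities exactly", {
  set.seed(70)
  n <- 200
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(0.5 * d$a - 1 * d$b))
  fit <- fit_logistic(d, y)
  # ranges chosen so |coef * span| has an exact 2:1 ratio
  spans <- abs(fit$coefficients)
  ranges <- list(a = c(0, 2 / spans[["a"]]), b = c(0, 1 / spans[["b"]]))
  nom <- build_nomogram(fit, feature_ranges = ranges)
  expect_equal(max(nom$scales$a$points), 100)
  expect_equal(max(nom$scales$b$points), 50)
  # single-feature model: that feature spans exactly 0-100
  fit1 <- fit_logistic(d["a"], y)
  nom1 <- build_nomogram(fit1)
  expect_equal(range(nom1$scales$a$points), c(0, 100))
  # total points -> probability identical to the direct prediction
  nom_d <- build_nomogram(fit)
  idx <- sample(n, 100)
  pts <- nomogram_points(nom_d, d[idx, , drop = FALSE])
  direct <- predict(fit, d[idx, , drop = FALSE])
  expect_lt(max(abs(pts$probability - direct)), 1e-6)
  # all-zero model rejected
  fake <- fit
  fake$coefficients[] <- 0
  expect_error(build_nomogram(fake), "zero")
})

test_that("calibration_bootstrap is near the identity for a well-specified model", {
  set.seed(80)
  n <- 2000
  d <- data.frame(x = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + 1.5 * d$x))
  fit <- fit_logistic(d, y)
  cal <- calibration_bootstrap(fit, n_boot = 40, seed = 2)
  expect_true(all(abs(cal$observed_corrected - cal$predicted) < 0.05))
  expect_equal(sum(cal$n), n)
  expect_error(calibration_bootstrap(fit, n_boot = 0), "n_boot")
})

test_that("squared (over-shrunk) probabilities show observed above predicted at low p", {
  set.seed(81)
  n <- 3000
  x <- rnorm(n)
  p_true <- plogis(x)
  y <- rbinom(n, 1, p_true)
  miscal <- structure(list(intercept = 0, coefficients = c(x = 1),
                           features = "x", fitted = p_true^2,
                           data = data.frame(x = x), labels = y,
                           converged = TRUE), class = "glym_logit")
  cal <- calibration_bootstrap(miscal, n_boot = 5, seed = 3)
  low <- cal$predicted < 0.3
  expect_true(any(low))
  expect_true(all(cal$observed[low] > cal$predicted[low]))
})

test_that("decision_curve implements net benefit with its reference curves", {
  y <- rep(c(0, 1), c(60, 40))   # prevalence 0.4
  # perfect probabilities: net benefit equals prevalence everywhere
  perfect <- as.numeric(y)
  dca <- decision_curve(perfect, y)
  expect_equal(dca$net_benefit, rep(0.4, nrow(dca)))
  expect_equal(dca$treat_none, rep(0, nrow(dca)))
  # treat-all at small pt tends to prevalence; crosses 0 at pt = prevalence
  expect_equal(dca$treat_all[1], 0.4 - 0.6 * 0.01 / 0.99)
  expect_lt(dca$treat_all[nrow(dca)], 0)
  # model NB formula at one threshold, by hand
  set.seed(90)
  p <- runif(100)
  pt <- 0.3
  treat <- p >= pt
  nb_hand <- sum(treat & y == 1) / 100 - sum(treat & y == 0) / 100 * pt / (1 - pt)
  expect_equal(decision_curve(p, y, thresholds = pt)$net_benefit, nb_hand)
  # an uninformative model cannot beat the best reference by more than noise
  set.seed(91)
  y2 <- rbinom(400, 1, 0.4)
  p2 <- runif(400)
  dca2 <- decision_curve(p2, y2)
  expect_true(all(dca2$net_benefit <= pmax(dca2$treat_all, 0) + 0.05))
  expect_error(decision_curve(p2, y2, thresholds = numeric(0)), "nonempty")
  expect_error(decision_curve(p2, y2, thresholds = c(0, 0.5)), "inside")
})
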