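# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (explicit pairing, brute-force counting, closed forms) so
# the package implementation is checked against a different route.

# Pearson r between gbold advanced by k samples and csf, by explicit
# index-shifted pairing and the raw sum formula.
brute_lag_pearson <- function(g, c, k) {
  n <- length(g)
  if (k >= 0) {
    x <- g[(1 + k):n]; y <- c[1:(n - k)]
  } else {
    x <- g[1:(n + k)]; y <- c[(1 - k):n]
  }
  m <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- sum(x * y) - sx * sy / m
  den <- sqrt((sum(x^2) - sx^2 / m) * (sum(y^2) - sy^2 / m))
  num / den
}

# AUC as the Mann-Whitney probability by brute-force pair counting,
# ties counted one half.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Closed-form AUC of two Gaussian classes (binormal model).
binormal_auc <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  stats::pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))
}

# Pooled-variance two-sample t statistic from the textbook formula.
pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# Partial correlation of x and y given c from a 3x3 correlation matrix.
closed_form_partial <- function(r_xy, r_xc, r_yc) {
  (r_xy - r_xc * r_yc) / sqrt((1 - r_xc^2) * (1 - r_yc^2))
}

# Asymptotic SEs of logistic coefficients at the true parameters:
# inverse Fisher information sum p(1-p) x x' over the design.
logistic_se <- function(X, beta) {
  p <- stats::plogis(drop(X %*% beta))
  info <- t(X) %*% (X * (p * (1 - p)))
  sqrt(diag(solve(info)))
}

sim_coupled_cohort <- function(n_subjects, coupling_strength, seed,
                               n_volumes = 74, tr = 2) {
  generate_signal_cohort(
    n_subjects,
    signal_config(n_volumes = n_volumes, tr = tr,
                  coupling_strength = coupling_strength, seed = seed))
}
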