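#' Lag-resolved gBOLD-CSF cross-correlation
#'
#' Computes the Pearson correlation between the gBOLD and CSF traces over a
#' symmetric lag grid (step = `tr`, default range +/- 10 s). The lag-sign
#' convention is fixed so that `r(L)` correlates the gBOLD sample at `t + L`
#' with the CSF sample at `t`: under the physiological relation
#' CSF = -d/dt gBOLD this yields a negative extremum at positive lag
#' (CSF peaks precede gBOLD peaks). Each lag's correlation is computed on
#' the overlapping segment with that segment's own means and SDs.
#'
#' @param gbold,csf [glym_ts()] objects of equal length (>= 32) and `tr`.
#' @param max_lag Maximum lag in seconds; must be a multiple of `tr` and
#'   leave at least 3 overlapping samples.
#' @return A data.frame of class `cross_correlogram` with columns `lag`
#'   (seconds, `-max_lag` to `+max_lag`) and `r`.
#' @examples
#' t <- seq(0, by = 2, length.out = 230)
#' cc <- cross_correlate(glym_ts(sin(2 * pi * t / 16), tr = 2),
#'                       glym_ts(-cos(2 * pi * t / 16), tr = 2), max_lag = 10)
#' cc[cc$lag == 4, ]  # r near -1
#' @export
cross_correlate <- function(gbold, csf, max_lag = 10) {
  ensure_ts(gbold)
  ensure_ts(csf)
  check_same_grid(gbold, csf)
  n <- length(gbold$values)
  if (n < 32L) stop("cross-correlation needs at least 32 samples")
  k_max <- max_lag / gbold$tr
  if (abs(k_max - round(k_max)) > 1e-8 || k_max < 0) {
    stop("'max_lag' must be a non-negative multiple of tr")
  }
  k_max <- as.integer(round(k_max))
  if (n - k_max < 3L) stop("'max_lag' leaves too few overlapping samples")
  ks <- (-k_max):k_max
  r <- vapply(ks, function(k) lag_cor(gbold$values, csf$values, k),
              numeric(1))
  structure(data.frame(lag = ks * gbold$tr, r = r),
            class = c("cross_correlogram", "data.frame"),
            tr = gbold$tr)
}

# r(k) = cor(gbold at t + k*tr, csf at t) on the overlapping segment.
lag_cor <- function(g, c, k) {
  n <- length(g)
  if (k >= 0) {
    stats::cor(g[(1 + k):n], c[1:(n - k)])
  } else {
    stats::cor(g[1:(n + k)], c[(1 - k):n])
  }
}

#' Coupling index from a cross-correlogram
#'
#' The scalar glymphatic coupling marker: the negation of the gBOLD-CSF
#' cross-correlation at the `index_lag` (+4 s by default, a quarter period
#' of the dominant low-frequency fluctuation), so stronger anticorrelation
#' at +4 s maps to a larger positive index. The negation is signed, not an
#' absolute value: subjects whose +4 s correlation is positive get a
#' negative index, which is what allows near-zero group means with sizable
#' SDs.
#'
#' @param cc A `cross_correlogram` from [cross_correlate()].
#' @param index_lag Lag in seconds at which the index is read (default 4);
#'   must be present on the lag grid.
#' @return The coupling index (dimensionless).
#' @export
coupling_index <- function(cc, index_lag = 4) {
  stopifnot(inherits(cc, "cross_correlogram"))
  i <- which(abs(cc$lag - index_lag) < 1e-8)
  if (length(i) != 1L) {
    stop(sprintf("lag %g s is not on the correlogram grid", index_lag))
  }
  -cc$r[i]
}

#' Zero-lag coupling with the negated gBOLD derivative
#'
#' Pearson correlation, at lag 0, between -d/dt gBOLD and the CSF trace —
#' the direct check of the inflow mechanism (falling global activity drives
#' CSF inflow).
#'
#' @param gbold,csf [glym_ts()] objects of equal length and `tr`.
#' @return Correlation in \[-1, 1\].
#' @export
derivative_coupling <- function(gbold, csf) {
  ensure_ts(gbold)
  ensure_ts(csf)
  check_same_grid(gbold, csf)
  if (length(gbold$values) < 32L) stop("needs at least 32 samples")
  stats::cor(-temporal_derivative(gbold)$values, csf$values)
}

#' Group-mean cross-correlogram
#'
#' Arithmetic mean of per-subject cross-correlograms, lag by lag. All
#' correlograms must share the same lag grid.
#'
#' @param correlograms A list of `cross_correlogram` objects.
#' @return A `cross_correlogram` with the per-lag mean `r`.
#' @export
group_mean_correlogram <- function(correlograms) {
  stopifnot(length(correlograms) >= 1L)
  lags <- correlograms[[1]]$lag
  rs <- vapply(correlograms, function(cc) {
    stopifnot(inherits(cc, "cross_correlogram"))
    if (length(cc$lag) != length(lags) || any(abs(cc$lag - lags) > 1e-8)) {
      stop("correlogram lag grids differ")
    }
    cc$r
  }, numeric(length(lags)))
  structure(data.frame(lag = lags, r = rowMeans(as.matrix(rs))),
            class = c("cross_correlogram", "data.frame"),
            tr = attr(correlograms[[1]], "tr"))
}

# Full subject x subject x lag cross-correlation array: R[i, j, l] is the
# lag-l correlation of subject i's gBOLD with subject j's CSF. Matrix cor()
# per lag keeps the permutation test O(draws) after this one precomputation.
pairwise_correlogram_array <- function(pairs, max_lag) {
  n_sub <- length(pairs)
  tr <- pairs[[1]]$gbold$tr
  n_t <- length(pairs[[1]]$gbold$values)
  G <- vapply(pairs, function(p) {
    ensure_ts(p$gbold)
    check_same_grid(p$gbold, p$csf)
    if (length(p$gbold$values) != n_t || abs(p$gbold$tr - tr) > 1e-12) {
      stop("all subjects must share series length and tr")
    }
    p$gbold$values
  }, numeric(n_t))
  C <- vapply(pairs, function(p) p$csf$values, numeric(n_t))
  k_max <- as.integer(round(max_lag / tr))
  ks <- (-k_max):k_max
  R <- array(NA_real_, c(n_sub, n_sub, length(ks)))
  for (li in seq_along(ks)) {
    k <- ks[li]
    if (k >= 0) {
      R[, , li] <- t(stats::cor(G[(1 + k):n_t, , drop = FALSE],
                                C[1:(n_t - k), , drop = FALSE]))
    } else {
      R[, , li] <- t(stats::cor(G[1:(n_t + k), , drop = FALSE],
                                C[(1 - k):n_t, , drop = FALSE]))
    }
  }
  list(R = R, lags = ks * tr, tr = tr)
}

#' Subject-reassignment permutation test of the group-mean correlogram
#'
#' Null model: gBOLD and CSF traces carry no subject-specific coupling, so
#' reassigning CSF traces across subjects leaves the group-mean
#' cross-correlogram unchanged in distribution. Each of `n_perm` draws
#' applies a uniformly random permutation (identity allowed) of the CSF
#' traces across subjects and recomputes the group-mean correlogram; the
#' per-lag two-sided p-value uses the add-one estimator
#' `(1 + #\{|null| >= |observed|\}) / (n_perm + 1)`, which can never return
#' zero, and the 95% band is the per-lag 2.5/97.5 percentile range of the
#' null means.
#'
#' @param pairs A list of subject signal pairs (`gbold`, `csf` [glym_ts()]
#'   elements, shared length and `tr`); at least 3 subjects.
#' @param max_lag Maximum lag in seconds (default 10).
#' @param n_perm Number of permutation draws (default 10000, >= 1).
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `permutation_null` with elements `lags`,
#'   `observed` (group-mean r per lag), `p` (two-sided per lag), `band95`
#'   (2 x n_lags matrix of percentiles), `n_perm`, `seed`.
#' @export
permutation_test <- function(pairs, max_lag = 10, n_perm = 10000, seed = 1L) {
  if (length(pairs) < 3L) stop("permutation test needs at least 3 subjects")
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("'n_perm' must be at least 1")
  pre <- pairwise_correlogram_array(pairs, max_lag)
  n_sub <- length(pairs)
  n_lag <- length(pre$lags)
  idx_diag <- cbind(seq_len(n_sub), seq_len(n_sub))
  observed <- vapply(seq_len(n_lag),
                     function(li) mean(pre$R[, , li][idx_diag]), numeric(1))
  set.seed(seed)
  null_means <- matrix(NA_real_, n_perm, n_lag)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n_sub)
    idx <- cbind(seq_len(n_sub), perm)
    for (li in seq_len(n_lag)) {
      null_means[b, li] <- mean(pre$R[, , li][idx])
    }
  }
  p <- vapply(seq_len(n_lag), function(li) {
    (1 + sum(abs(null_means[, li]) >= abs(observed[li]))) / (n_perm + 1)
  }, numeric(1))
  band95 <- apply(null_means, 2, stats::quantile, probs = c(0.025, 0.975),
                  names = FALSE)
  structure(list(lags = pre$lags, observed = observed, p = p,
                 band95 = band95, n_perm = n_perm, seed = as.integer(seed)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> %d lags, %d draws (seed %d)\n",
              length(x$lags), x$n_perm, x$seed))
  print(data.frame(lag = x$lags, observed = round(x$observed, 4),
                   p = signif(x$p, 3)))
  invisible(x)
}

#' Per-subject coupling results for a cohort of signal pairs
#'
#' Runs the standard temporal preprocessing and the coupling computation on
#' every subject: discard, detrend, band-pass, z-score, then the lagged
#' cross-correlogram, the coupling index at `index_lag`, and the zero-lag
#' derivative coupling.
#'
#' @param pairs A list of subject signal pairs.
#' @param n_discard,low,high Preprocessing parameters, see [prep_signal()].
#' @param max_lag,index_lag Correlogram range and index lag in seconds.
#' @return A list with `results` (data.frame: `subject`, `coupling_index`,
#'   `derivative_r0`), `correlograms` (list), and `prepped` (list of
#'   preprocessed pairs, reusable by [permutation_test()]).
#' @export
cohort_coupling <- function(pairs, n_discard = 10, low = 0.01, high = 0.1,
                            max_lag = 10, index_lag = 4) {
  prepped <- lapply(pairs, function(p) {
    list(gbold = prep_signal(p$gbold, n_discard, low, high),
         csf = prep_signal(p$csf, n_discard, low, high))
  })
  ccs <- lapply(prepped, function(p) cross_correlate(p$gbold, p$csf, max_lag))
  results <- data.frame(
    subject = seq_along(pairs),
    coupling_index = vapply(ccs, coupling_index, numeric(1),
                            index_lag = index_lag),
    derivative_r0 = vapply(prepped, function(p)
      derivative_coupling(p$gbold, p$csf), numeric(1))
  )
  list(results = results, correlograms = ccs, prepped = prepped)
}
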