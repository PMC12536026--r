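#' Marker distribution specification
#'
#' One marker's marginal distribution in one group: normal (`mean`, `sd`) or
#' log-normal (`meanlog`, `sdlog`, set `lognormal = TRUE`). Log-normal
#' marginals serve skewed volumetry summaries reported as median (IQR).
#'
#' @param mean,sd Normal parameters (ignored when `lognormal = TRUE`).
#' @param lognormal Use a log-normal marginal.
#' @param meanlog,sdlog Log-scale parameters when `lognormal = TRUE`.
#' @return A list of class `marker_spec`.
#' @seealso [lnorm_from_quartiles()]
#' @export
marker_spec <- function(mean = NULL, sd = NULL, lognormal = FALSE,
                        meanlog = NULL, sdlog = NULL) {
  if (lognormal) {
    stopifnot(is.numeric(meanlog), is.numeric(sdlog), sdlog > 0)
  } else {
    stopifnot(is.numeric(mean), is.numeric(sd), sd > 0)
  }
  structure(list(mean = mean, sd = sd, lognormal = lognormal,
                 meanlog = meanlog, sdlog = sdlog),
            class = "marker_spec")
}

#' Log-normal parameters from a median and quartiles
#'
#' Solves for the log-normal whose median and quartiles match a reported
#' median (IQR) summary: `meanlog = log(median)`,
#' `sdlog = log(q75/q25) / (2 * qnorm(0.75))`.
#'
#' @param q25,median,q75 Positive quartile summaries with `q25 < median < q75`.
#' @return A log-normal [marker_spec()].
#' @examples
#' lnorm_from_quartiles(0.05, 0.06, 0.07)  # HC choroid plexus volume fraction
#' @export
lnorm_from_quartiles <- function(q25, median, q75) {
  stopifnot(q25 > 0, q25 < median, median < q75)
  marker_spec(lognormal = TRUE, meanlog = log(median),
              sdlog = log(q75 / q25) / (2 * stats::qnorm(0.75)))
}

# Map standard-normal draws through a marker_spec marginal.
marker_quantile <- function(spec, z) {
  if (spec$lognormal) {
    stats::qlnorm(stats::pnorm(z), spec$meanlog, spec$sdlog)
  } else {
    spec$mean + spec$sd * z
  }
}

#' Synthetic cohort configuration
#'
#' Defaults encode the case-control cohort this package targets: 41 ALS
#' patients and 43 healthy controls (HC) with group marker distributions
#' matching the published summary table — ALPS index 1.20 +/- 0.16 (ALS)
#' vs 1.36 +/- 0.14 (HC); gBOLD-CSF coupling index 0.01 +/- 0.13 vs
#' 0.16 +/- 0.14; choroid plexus volume (CPV) fraction 0.09 +/- 0.03%
#' (ALS, normal) vs median 0.06% IQR (0.05, 0.07)% (HC, log-normal);
#' total intracranial volume (TIV) 1598 +/- 174 vs 1605 +/- 148 ml.
#' Within the ALS group, ALPS and the CPV fraction are drawn with Pearson
#' correlation `als_correlation` (default -0.537) through a Gaussian
#' copula; the HC group defaults to independence (`hc_correlation = 0`)
#' because no within-HC marker correlation structure is reported.
#' CPV in ml is derived as `cpv_fraction/100 * tiv`, so the fraction
#' identity `cpv_fraction = 100 * cpv / tiv` holds exactly per subject.
#'
#' @param n_als,n_hc Group sizes (each >= 2).
#' @param alps_als,alps_hc,coupling_als,coupling_hc,cpv_fraction_als,cpv_fraction_hc,tiv_als,tiv_hc
#'   [marker_spec()] marginals per marker and group.
#' @param als_correlation,hc_correlation Within-group ALPS-CPVfraction
#'   correlation, strictly inside (-1, 1).
#' @param alsfrs_mean,alsfrs_sd ALSFRS-R distribution (points; samples
#'   clipped to the 0-48 scale range).
#' @param duration_meanlog,duration_sdlog Log-normal disease duration in
#'   months (moment-matched by default to mean 20.8, SD 13.3; strictly
#'   positive by construction).
#' @param bulbar_fraction Probability of bulbar (vs limb) onset.
#' @param seed Integer seed; every draw flows from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_als = 41, n_hc = 43,
                          alps_als = marker_spec(1.20, 0.16),
                          alps_hc = marker_spec(1.36, 0.14),
                          coupling_als = marker_spec(0.01, 0.13),
                          coupling_hc = marker_spec(0.16, 0.14),
                          cpv_fraction_als = marker_spec(0.09, 0.03),
                          cpv_fraction_hc = lnorm_from_quartiles(0.05, 0.06, 0.07),
                          tiv_als = marker_spec(1598, 174),
                          tiv_hc = marker_spec(1605, 148),
                          als_correlation = -0.537,
                          hc_correlation = 0,
                          alsfrs_mean = 33.2, alsfrs_sd = 6.0,
                          duration_meanlog = log(20.8) - 0.5 * log(1 + (13.3 / 20.8)^2),
                          duration_sdlog = sqrt(log(1 + (13.3 / 20.8)^2)),
                          bulbar_fraction = 9 / 41,
                          seed = 1L) {
  for (rho in c(als_correlation, hc_correlation)) {
    if (!is.numeric(rho) || abs(rho) >= 1) {
      stop("marker correlations must have magnitude < 1")
    }
  }
  if (n_als < 2 || n_hc < 2) stop("each group needs at least 2 subjects")
  stopifnot(alsfrs_sd > 0, duration_sdlog > 0,
            bulbar_fraction >= 0, bulbar_fraction <= 1)
  cfg <- list(n_als = as.integer(n_als), n_hc = as.integer(n_hc),
              alps_als = alps_als, alps_hc = alps_hc,
              coupling_als = coupling_als, coupling_hc = coupling_hc,
              cpv_fraction_als = cpv_fraction_als,
              cpv_fraction_hc = cpv_fraction_hc,
              tiv_als = tiv_als, tiv_hc = tiv_hc,
              als_correlation = als_correlation,
              hc_correlation = hc_correlation,
              alsfrs_mean = alsfrs_mean, alsfrs_sd = alsfrs_sd,
              duration_meanlog = duration_meanlog,
              duration_sdlog = duration_sdlog,
              bulbar_fraction = bulbar_fraction,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

# Draw one group's marker block: (alps, cpv_fraction) via Gaussian copula,
# independent coupling and TIV; returns a data.frame.
draw_group <- function(n, alps_spec, cpvf_spec, coupling_spec, tiv_spec, rho) {
  z <- matrix(stats::rnorm(2 * n), ncol = 2)
  z2 <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  data.frame(
    alps_index = marker_quantile(alps_spec, z[, 1]),
    cpv_fraction_pct = marker_quantile(cpvf_spec, z2),
    coupling_index = marker_quantile(coupling_spec, stats::rnorm(n)),
    tiv_ml = marker_quantile(tiv_spec, stats::rnorm(n))
  )
}

#' Generate a synthetic subject marker table
#'
#' Draws a full case-control marker table with the statistical structure the
#' downstream analysis assumes: configured group marginals for the ALPS
#' index, coupling index, CPV fraction and TIV; a Gaussian-copula
#' correlation between ALPS and CPV fraction within each group; clinical
#' fields (ALSFRS-R clipped to 0-48, strictly positive log-normal disease
#' duration, onset site) for the ALS rows; and demographics (age, sex, BMI,
#' education) carried for table parity but never consumed by any
#' computation. The progression rate is computed from the drawn ALSFRS-R
#' and duration via [progression_rate()].
#'
#' @param config A [cohort_config()].
#' @return A data.frame with one row per subject (ALS rows first) and
#'   columns `subject_id, group, age, sex, bmi, education_years, alsfrs_r,
#'   duration_months, onset, progression_rate, alps_index, coupling_index,
#'   cpv_ml, tiv_ml, cpv_fraction_pct`. The configuration (including the
#'   seed) is attached as attribute `"config"`.
#' @examples
#' tab <- generate_marker_table(cohort_config(seed = 42))
#' aggregate(alps_index ~ group, tab, mean)
#' @export
generate_marker_table <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_als <- config$n_als
  n_hc <- config$n_hc

  als <- draw_group(n_als, config$alps_als, config$cpv_fraction_als,
                    config$coupling_als, config$tiv_als,
                    config$als_correlation)
  hc <- draw_group(n_hc, config$alps_hc, config$cpv_fraction_hc,
                   config$coupling_hc, config$tiv_hc,
                   config$hc_correlation)
  markers <- rbind(als, hc)
  markers$cpv_ml <- markers$cpv_fraction_pct / 100 * markers$tiv_ml

  n <- n_als + n_hc
  group <- rep(c("ALS", "HC"), c(n_als, n_hc))
  # Demographics: matched groups (age 58.6 +/- 9.6 vs 55.8 +/- 5.8 years,
  # ~66% male, BMI ~23.5); decorative columns only.
  age <- round(ifelse(group == "ALS", stats::rnorm(n, 58.6, 9.6),
                      stats::rnorm(n, 55.8, 5.8)), 1)
  sex <- ifelse(stats::runif(n) < 27 / 41, "M", "F")
  bmi <- round(ifelse(group == "ALS", stats::rnorm(n, 23.4, 2.8),
                      stats::rnorm(n, 23.8, 2.5)), 1)
  education <- pmax(0, round(ifelse(group == "ALS", stats::rnorm(n, 9.5, 4),
                                    stats::rnorm(n, 11, 3))))

  alsfrs <- pmin(48, pmax(0, round(
    stats::rnorm(n_als, config$alsfrs_mean, config$alsfrs_sd), 1)))
  duration <- round(stats::rlnorm(n_als, config$duration_meanlog,
                                  config$duration_sdlog), 1)
  duration <- pmax(duration, 0.1)  # guard against rounding to zero
  onset <- ifelse(stats::runif(n_als) < config$bulbar_fraction,
                  "bulbar", "limb")

  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group,
    age = age, sex = sex, bmi = bmi, education_years = education,
    alsfrs_r = c(alsfrs, rep(NA_real_, n_hc)),
    duration_months = c(duration, rep(NA_real_, n_hc)),
    onset = c(onset, rep(NA_character_, n_hc)),
    progression_rate = c(progression_rate(alsfrs, duration),
                         rep(NA_real_, n_hc)),
    alps_index = markers$alps_index,
    coupling_index = markers$coupling_index,
    cpv_ml = markers$cpv_ml,
    tiv_ml = markers$tiv_ml,
    cpv_fraction_pct = markers$cpv_fraction_pct,
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  out
}

#' Coupled signal-pair configuration
#'
#' Parameters of the physiological toy model behind [generate_signal_pair()]:
#' the gBOLD trace is narrowband Gaussian noise with a spectral peak at
#' `dominant_freq` strictly inside the passband, and the CSF inflow trace is
#' a `coupling_strength`-weighted mixture of the negated, unit-variance
#' gBOLD time derivative and white noise. The default dominant frequency
#' 1/16 Hz places the cross-correlation extrema of the derivative relation
#' at +/- 4 s (a quarter period) on a 2-s sampling grid.
#'
#' @param n_volumes Series length before any volume discard (default 240).
#' @param tr Sampling interval in seconds (default 2).
#' @param passband Band edges in Hz (default `c(0.01, 0.1)`).
#' @param dominant_freq Spectral peak of the gBOLD trace in Hz
#'   (default 1/16); must lie strictly inside the passband.
#' @param bandwidth Gaussian spectral width (SD, Hz) around the peak
#'   (default 0.02).
#' @param coupling_strength Fraction of CSF variance explained by
#'   -d/dt gBOLD, in \[0, 1\] (default 0.8).
#' @param rectify_csf Half-wave rectify the CSF trace (inflow is one-sided
#'   in reality); default `FALSE` so closed-form sinusoid checks hold.
#' @param seed Integer seed.
#' @return A list of class `signal_config`.
#' @export
signal_config <- function(n_volumes = 240, tr = 2, passband = c(0.01, 0.1),
                          dominant_freq = 1 / 16, bandwidth = 0.02,
                          coupling_strength = 0.8, rectify_csf = FALSE,
                          seed = 1L) {
  nyq <- 1 / (2 * tr)
  if (!(passband[1] > 0 && passband[1] < dominant_freq &&
        dominant_freq < passband[2] && passband[2] < nyq)) {
    stop(sprintf(
      "need 0 < low < dominant_freq < high < Nyquist; got band (%g, %g), peak %g, Nyquist %g",
      passband[1], passband[2], dominant_freq, nyq))
  }
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("'coupling_strength' must lie in [0, 1]")
  }
  stopifnot(n_volumes >= 32, bandwidth > 0)
  structure(list(n_volumes = as.integer(n_volumes), tr = tr,
                 passband = passband, dominant_freq = dominant_freq,
                 bandwidth = bandwidth, coupling_strength = coupling_strength,
                 rectify_csf = isTRUE(rectify_csf), seed = as.integer(seed)),
            class = "signal_config")
}

# Narrowband Gaussian series: white Gaussian DFT coefficients shaped by a
# Gaussian bump at f0 and hard-zeroed outside [low, high], so the series'
# spectral mass outside the passband is exactly zero on its own grid.
narrowband_noise <- function(n, tr, low, high, f0, bw) {
  freqs <- (seq_len(n) - 1) / (n * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)
  w <- exp(-(freqs - f0)^2 / (2 * bw^2))
  w[freqs < low | freqs > high] <- 0
  xf <- stats::fft(stats::rnorm(n)) * w
  x <- Re(stats::fft(xf, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Generate a coupled gBOLD/CSF signal pair
#'
#' Simulates the empirical relation the coupling analysis is built on:
#' decreasing global brain activity is followed by CSF inflow, i.e. the CSF
#' trace tracks the negated time derivative of the gBOLD trace. With
#' `coupling_strength` s, `csf = sqrt(s) * scale(-d/dt gbold) +
#' sqrt(1-s) * white noise`, optionally half-wave rectified.
#'
#' @param config A [signal_config()].
#' @return A list with elements `gbold` and `csf`, both [glym_ts()] of
#'   length `n_volumes` at spacing `tr`; the configuration is attached as
#'   attribute `"config"`.
#' @examples
#' pair <- generate_signal_pair(signal_config(coupling_strength = 1, seed = 3))
#' d <- temporal_derivative(pair$gbold)
#' cor(-d$values, pair$csf$values)  # ~ 1
#' @export
generate_signal_pair <- function(config = signal_config()) {
  stopifnot(inherits(config, "signal_config"))
  set.seed(config$seed)
  n <- config$n_volumes
  g <- narrowband_noise(n, config$tr, config$passband[1], config$passband[2],
                        config$dominant_freq, config$bandwidth)
  gbold <- glym_ts(g, tr = config$tr)
  d <- temporal_derivative(gbold)$values
  d <- (d - mean(d)) / stats::sd(d)
  s <- config$coupling_strength
  csf <- sqrt(s) * (-d) + sqrt(1 - s) * stats::rnorm(n)
  if (config$rectify_csf) csf <- pmax(csf, 0)
  out <- list(gbold = gbold, csf = glym_ts(csf, tr = config$tr))
  attr(out, "config") <- config
  out
}

#' Embed a signal pair in a toy 4-D phantom
#'
#' Builds a small 4-D image in which voxels under the gray-matter mask carry
#' the gBOLD trace plus i.i.d. Gaussian noise, voxels under the CSF mask
#' carry the CSF trace plus noise, and all remaining voxels carry pure
#' noise. Mask-mean extraction ([extract_mask_mean()]) then recovers each
#' series with residual SD ~ `noise_sd / sqrt(k)` for a k-voxel mask.
#'
#' @param pair A list with `gbold` and `csf` [glym_ts()] elements, as
#'   returned by [generate_signal_pair()].
#' @param grid_shape Integer vector of 3 spatial dimensions (default
#'   `c(6, 6, 4)`).
#' @param gm_mask,csf_mask Optional 3-D logical arrays on `grid_shape`;
#'   must be disjoint and nonempty. Defaults split the top and bottom
#'   z-slabs.
#' @param noise_sd Voxelwise noise SD (>= 0).
#' @param seed Integer seed for the voxel noise.
#' @return A list `image4d` (4-D array), `gm_mask`, `csf_mask`.
#' @export
generate_phantom <- function(pair, grid_shape = c(6, 6, 4),
                             gm_mask = NULL, csf_mask = NULL,
                             noise_sd = 0.1, seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1), noise_sd >= 0)
  if (is.null(gm_mask)) {
    gm_mask <- array(FALSE, grid_shape)
    gm_mask[, , seq_len(ceiling(grid_shape[3] / 2))] <- TRUE
  }
  if (is.null(csf_mask)) {
    csf_mask <- array(FALSE, grid_shape)
    csf_mask[, , (ceiling(grid_shape[3] / 2) + 1):grid_shape[3]] <- TRUE
  }
  gm_mask <- as.array(gm_mask) != 0
  csf_mask <- as.array(csf_mask) != 0
  if (!all(dim(gm_mask) == grid_shape) || !all(dim(csf_mask) == grid_shape)) {
    stop("mask dimensions must equal 'grid_shape'")
  }
  if (!any(gm_mask) || !any(csf_mask)) stop("masks must be nonempty")
  if (any(gm_mask & csf_mask)) stop("gray-matter and CSF masks overlap")
  check_same_grid(pair$gbold, pair$csf)
  nt <- length(pair$gbold$values)
  set.seed(seed)
  nvox <- prod(grid_shape)
  img <- matrix(stats::rnorm(nvox * nt, sd = noise_sd), nrow = nvox)
  img[as.vector(gm_mask), ] <- sweep(
    img[as.vector(gm_mask), , drop = FALSE], 2, pair$gbold$values, "+")
  img[as.vector(csf_mask), ] <- sweep(
    img[as.vector(csf_mask), , drop = FALSE], 2, pair$csf$values, "+")
  list(image4d = array(img, c(grid_shape, nt)),
       gm_mask = gm_mask, csf_mask = csf_mask)
}

#' Generate a cohort of coupled signal pairs
#'
#' Convenience wrapper: one [generate_signal_pair()] per subject with
#' per-subject seeds derived deterministically from `config$seed`.
#'
#' @param n_subjects Number of subjects.
#' @param config A [signal_config()] template; its `seed` anchors the
#'   per-subject seed stream.
#' @return A list of `n_subjects` signal pairs.
#' @export
generate_signal_cohort <- function(n_subjects, config = signal_config()) {
  stopifnot(n_subjects >= 1)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, n_subjects)
  lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    generate_signal_pair(cfg)
  })
}
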