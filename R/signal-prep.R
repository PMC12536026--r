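#' Discard initial volumes of a signal
#'
#' Drops the first `n_discard` samples of a trace, mirroring the removal of
#' pre-equilibrium volumes at the start of an fMRI run (signal intensity is
#' unstable until longitudinal magnetization reaches steady state). The time
#' origin advances by `n_discard * tr` so absolute timing is preserved.
#'
#' @param ts A [glym_ts()] object.
#' @param n_discard Number of leading samples to drop (non-negative integer,
#'   strictly less than the series length).
#' @return A shorter `glym_ts`.
#' @examples
#' ts <- glym_ts(rnorm(240), tr = 2)
#' length(discard_initial(ts, 10))  # 230
#' @export
discard_initial <- function(ts, n_discard) {
  ensure_ts(ts)
  n_discard <- as.integer(n_discard)
  if (length(n_discard) != 1L || is.na(n_discard) || n_discard < 0L) {
    stop("'n_discard' must be a single non-negative integer")
  }
  n <- length(ts$values)
  if (n_discard >= n) {
    stop(sprintf("cannot discard %d volumes from a %d-volume series",
                 n_discard, n))
  }
  if (n_discard == 0L) return(ts)
  glym_ts(ts$values[-seq_len(n_discard)], tr = ts$tr,
          t0 = ts$t0 + n_discard * ts$tr)
}

#' Remove the least-squares linear trend
#'
#' Fits and subtracts `a + b t` so the output is orthogonal to both the
#' constant and the linear ramp (slow scanner drift removal).
#'
#' @param ts A [glym_ts()] object of length >= 3.
#' @return A detrended `glym_ts` with unchanged `tr` and length.
#' @export
detrend_linear <- function(ts) {
  ensure_ts(ts)
  n <- length(ts$values)
  if (n < 3L) stop("detrending needs at least 3 samples")
  t <- ts_times(ts)
  fit <- stats::lm.fit(cbind(1, t), ts$values)
  glym_ts(as.numeric(fit$residuals), tr = ts$tr, t0 = ts$t0)
}

#' Zero-phase band-pass filter
#'
#' Restricts a trace to a frequency band, by default 0.01-0.1 Hz, the
#' low-frequency range in which the global BOLD signal tracks CSF inflow.
#' The default realization is an ideal spectral mask: DFT bins outside the
#' band are zeroed, which is exactly zero-phase (no group delay, so lag
#' estimates downstream are unbiased) and exactly idempotent. A 2nd-order
#' Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`, effective 4th order, also zero-phase) is available
#' via `method = "butterworth"`; its gentle passband droop makes repeated
#' filtering attenuate band-edge content slightly. Both realizations meet
#' the same amplitude contract (passband tones keep >= 90% of their
#' amplitude, tones at twice the upper edge are attenuated to <= 10%).
#'
#' @param ts A [glym_ts()] object, length >= 32.
#' @param low,high Band edges in Hz; `0 < low < high < 1/(2 tr)` (Nyquist).
#' @param method `"fft"` (default) or `"butterworth"`.
#' @return The filtered `glym_ts` (mean removed by construction).
#' @examples
#' ts <- glym_ts(sin(2 * pi * 0.05 * seq(0, by = 2, length.out = 230)), tr = 2)
#' filtered <- bandpass(ts, 0.01, 0.1)
#' @export
bandpass <- function(ts, low = 0.01, high = 0.1,
                     method = c("fft", "butterworth")) {
  ensure_ts(ts)
  method <- match.arg(method)
  n <- length(ts$values)
  if (n < 32L) stop("band-pass filtering needs at least 32 samples")
  nyq <- 1 / (2 * ts$tr)
  if (!(low > 0 && low < high && high < nyq)) {
    stop(sprintf("band (%g, %g) Hz must satisfy 0 < low < high < Nyquist = %g Hz",
                 low, high, nyq))
  }
  x <- ts$values - mean(ts$values)
  if (method == "butterworth") {
    bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
    y <- signal::filtfilt(bf, x)
  } else {
    y <- fft_band_mask(x, ts$tr, low, high)
  }
  glym_ts(as.numeric(y), tr = ts$tr, t0 = ts$t0)
}

# Hard spectral mask: zero every DFT bin whose frequency falls outside
# [low, high]; exactly zero-phase and idempotent.
fft_band_mask <- function(x, tr, low, high) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) / (n * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= low & freqs <= high
  xf <- stats::fft(x)
  xf[!keep] <- 0
  Re(stats::fft(xf, inverse = TRUE)) / n
}

#' Mean signal over a mask
#'
#' Extracts a single trace from a 4-D image by averaging, at each timepoint,
#' the voxels selected by a 3-D mask — the operation used to pull the global
#' gray-matter BOLD signal from a cortical mask and the CSF inflow signal
#' from a ventricle/bottom-slice mask.
#'
#' @param image4d 4-D numeric array (x, y, z, time), e.g. as returned by
#'   `RNifti::readNifti()` coerced with `as.array()`.
#' @param mask 3-D logical or 0/1 array on the same spatial grid; must
#'   select at least one voxel.
#' @param tr Sampling interval of the time axis in seconds.
#' @param t0 Time of the first volume (seconds), default 0.
#' @return A `glym_ts` of length `dim(image4d)[4]`.
#' @export
extract_mask_mean <- function(image4d, mask, tr, t0 = 0) {
  image4d <- as.array(image4d)
  mask <- as.array(mask)
  if (length(dim(image4d)) != 4L) stop("'image4d' must be a 4-D array")
  if (length(dim(mask)) != 3L) stop("'mask' must be a 3-D array")
  if (!all(dim(image4d)[1:3] == dim(mask))) {
    stop("mask grid does not match the image grid")
  }
  mask <- mask != 0
  k <- sum(mask)
  if (k == 0L) stop("mask selects no voxels")
  nt <- dim(image4d)[4]
  flat <- matrix(image4d, ncol = nt)
  vals <- colMeans(flat[as.vector(mask), , drop = FALSE])
  glym_ts(vals, tr = tr, t0 = t0)
}

#' Temporal derivative of a signal
#'
#' Finite-difference d/dt: central differences in the interior, one-sided
#' differences at the two ends. Units are amplitude per second. The negated
#' derivative of the global BOLD signal is the physiological template for
#' the CSF inflow signal: falling global activity lowers cerebral blood
#' volume and pressure, drawing CSF into the imaging volume.
#'
#' @param ts A [glym_ts()] object of length >= 3.
#' @return A `glym_ts` of the same length and `tr`.
#' @export
temporal_derivative <- function(ts) {
  ensure_ts(ts)
  x <- ts$values
  n <- length(x)
  if (n < 3L) stop("derivative needs at least 3 samples")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / ts$tr
  d[n] <- (x[n] - x[n - 1]) / ts$tr
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * ts$tr)
  glym_ts(d, tr = ts$tr, t0 = ts$t0)
}

#' Standardize a signal to zero mean and unit variance
#'
#' Pearson correlation is scale-invariant, so this is cosmetic for the
#' coupling computation, but the pipeline fixes it for reproducible signal
#' files and plots.
#'
#' @param ts A [glym_ts()] object with non-constant values.
#' @return A z-scored `glym_ts`.
#' @export
zscore <- function(ts) {
  ensure_ts(ts)
  s <- stats::sd(ts$values)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant series")
  glym_ts((ts$values - mean(ts$values)) / s, tr = ts$tr, t0 = ts$t0)
}

#' Standard temporal preprocessing for one signal
#'
#' Convenience composition of the per-signal pipeline: discard initial
#' volumes, remove the linear trend, band-pass, z-score.
#'
#' @param ts A [glym_ts()] object.
#' @param n_discard Leading volumes to drop (default 10).
#' @param low,high Band edges in Hz (default 0.01 and 0.1).
#' @param method Filter realization, see [bandpass()].
#' @return The preprocessed `glym_ts`.
#' @export
prep_signal <- function(ts, n_discard = 10, low = 0.01, high = 0.1,
                        method = c("fft", "butterworth")) {
  ts <- discard_initial(ts, n_discard)
  ts <- detrend_linear(ts)
  ts <- bandpass(ts, low, high, method = match.arg(method))
  zscore(ts)
}
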