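#' Uniformly sampled 1-D signal
#'
#' Light container for an extracted fMRI signal trace (gBOLD or CSF inflow):
#' a numeric vector plus its sampling interval and time origin. All temporal
#' operations in the package consume and return this class.
#'
#' @param values Numeric vector of signal amplitudes (arbitrary units), no
#'   missing values.
#' @param tr Sampling interval in seconds (repetition time), a single
#'   positive number.
#' @param t0 Time of the first sample in seconds (advances when initial
#'   volumes are discarded). Default 0.
#' @return An object of class `glym_ts`.
#' @examples
#' ts <- glym_ts(sin(2 * pi * (0:119) / 16), tr = 2)
#' length(ts$values)
#' @export
glym_ts <- function(values, tr, t0 = 0) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("time series must not contain missing values")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) {
    stop("'tr' must be a single positive number (seconds)")
  }
  structure(list(values = values, tr = tr, t0 = as.numeric(t0)),
            class = "glym_ts")
}

#' @export
print.glym_ts <- function(x, ...) {
  cat(sprintf("<glym_ts> %d samples, tr = %g s, t0 = %g s\n",
              length(x$values), x$tr, x$t0))
  invisible(x)
}

#' @export
length.glym_ts <- function(x) length(x$values)

#' Sample times of a time series
#'
#' @param ts A [glym_ts()] object.
#' @return Numeric vector `t0 + (0:(n-1)) * tr` in seconds.
#' @export
ts_times <- function(ts) {
  stopifnot(inherits(ts, "glym_ts"))
  ts$t0 + (seq_along(ts$values) - 1) * ts$tr
}

ensure_ts <- function(ts, arg = deparse(substitute(ts))) {
  if (!inherits(ts, "glym_ts")) {
    stop(sprintf("'%s' must be a glym_ts object", arg))
  }
  ts
}

check_same_grid <- function(a, b) {
  if (length(a$values) != length(b$values)) {
    stop("time series lengths differ")
  }
  if (abs(a$tr - b$tr) > 1e-12) stop("time series sampling intervals differ")
  invisible(TRUE)
}
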