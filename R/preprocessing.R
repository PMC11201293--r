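#' Time-series matrix container
#'
#' Thin wrapper pairing a time x signals matrix (voxels or parcels) with its
#' repetition time. All temporal preprocessing operates on this.
#'
#' @param data numeric matrix, rows = time points, cols = signals.
#' @param tr_seconds repetition time in seconds.
#' @return a `ts_matrix`.
#' @export
ts_matrix <- function(data, tr_seconds) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (anyNA(data)) stop("missing values are not allowed")
  if (nrow(data) < 2) stop("need at least 2 time points")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  structure(list(data = data, tr_seconds = tr_seconds), class = "ts_matrix")
}

as_ts_matrix <- function(x, tr_seconds = NULL) {
  if (inherits(x, "ts_matrix")) return(x)
  ts_matrix(x, tr_seconds)
}

#' Drop initial volumes for signal equilibrium
#'
#' @param x a `ts_matrix` (or matrix with `tr_seconds`).
#' @param n_drop number of leading time points to remove (default 10, taking
#'   a 240-volume acquisition to 230 analyzed time points).
#' @param tr_seconds repetition time when `x` is a bare matrix.
#' @return a `ts_matrix` with `n_drop` fewer rows.
#' @export
drop_initial_volumes <- function(x, n_drop = 10L, tr_seconds = NULL) {
  x <- as_ts_matrix(x, tr_seconds)
  n_drop <- as.integer(n_drop)
  if (n_drop < 0) stop("n_drop must be non-negative")
  if (nrow(x$data) <= n_drop)
    stop(sprintf("cannot drop %d of %d time points", n_drop, nrow(x$data)))
  if (n_drop == 0) return(x)
  ts_matrix(x$data[-seq_len(n_drop), , drop = FALSE], x$tr_seconds)
}

#' Remove per-column linear trends
#'
#' Least-squares line (intercept + slope) removed from every column; output
#' columns have zero mean and zero linear trend.
#'
#' @inheritParams drop_initial_volumes
#' @return a detrended `ts_matrix`.
#' @export
detrend_linear <- function(x, tr_seconds = NULL) {
  x <- as_ts_matrix(x, tr_seconds)
  Tn <- nrow(x$data)
  if (Tn < 3) stop("need at least 3 time points to detrend")
  t <- seq_len(Tn)
  X <- cbind(1, t - mean(t))
  beta <- solve(crossprod(X), crossprod(X, x$data))
  ts_matrix(x$data - X %*% beta, x$tr_seconds)
}

fft_freqs <- function(n, tr) (seq_len(n) - 1) / (n * tr)

#' Ideal band-pass filter in the FFT domain
#'
#' Frequency bins with `low_hz <= f <= high_hz` (band edges inclusive) are
#' retained, all others — including DC — are zeroed, and the inverse transform
#' is returned. Within the pass band the filter is exactly power-preserving.
#'
#' @inheritParams drop_initial_volumes
#' @param low_hz,high_hz band edges in Hz (defaults 0.01 and 0.1).
#' @return a filtered `ts_matrix`.
#' @export
bandpass <- function(x, low_hz = 0.01, high_hz = 0.1, tr_seconds = NULL) {
  x <- as_ts_matrix(x, tr_seconds)
  Tn <- nrow(x$data)
  nyq <- 1 / (2 * x$tr_seconds)
  if (low_hz <= 0 || high_hz > nyq + 1e-12 || low_hz >= high_hz)
    stop(sprintf("band (%g, %g] Hz must lie within (0, Nyquist = %g]",
                 low_hz, high_hz, nyq))
  f <- fft_freqs(Tn, x$tr_seconds)
  fo <- pmin(f, 1 / x$tr_seconds - f)  # folded (two-sided) frequency
  keep <- fo >= low_hz - 1e-12 & fo <= high_hz + 1e-12
  keep[1] <- FALSE  # DC always removed
  Y <- stats::mvfft(x$data)
  Y[!keep, ] <- 0
  ts_matrix(Re(stats::mvfft(Y, inverse = TRUE)) / Tn, x$tr_seconds)
}

#' Standard temporal preprocessing chain
#'
#' Drop leading volumes, remove linear trends, band-pass filter. The
#' detrended-but-unfiltered series is kept alongside the filtered one because
#' fALFF needs a full-spectrum denominator while regional homogeneity, degree
#' centrality and the dynamic analyses use the filtered series.
#'
#' @inheritParams drop_initial_volumes
#' @param low_hz,high_hz pass band in Hz.
#' @return list with `detrended` and `filtered` `ts_matrix` objects.
#' @export
preprocess_series <- function(x, n_drop = 10L, low_hz = 0.01, high_hz = 0.1,
                              tr_seconds = NULL) {
  x <- drop_initial_volumes(x, n_drop, tr_seconds)
  det <- detrend_linear(x)
  list(detrended = det, filtered = bandpass(det, low_hz, high_hz))
}
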