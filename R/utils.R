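# Shared numerical utilities: smoothing, derivatives, peak logic, small helpers.

#' Zero-phase low-pass smoothing
#'
#' Forward-backward (zero-phase) 2nd-order Butterworth low-pass, used before
#' any differencing so that derivative zero crossings are not dominated by
#' sample-to-sample noise.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cut-off frequency in Hz (default 15, well above pulse
#'   harmonics of interest but below wideband noise).
#' @return Smoothed series of the same length.
#' @keywords internal
lowpass_smooth <- function(x, fs, cutoff = 15) {
  stopifnot(is.numeric(x), fs > 0)
  if (cutoff >= fs / 2) return(x)
  n <- length(x)
  # filtfilt needs some run length; fall back to a light running mean
  if (n < 24) {
    k <- max(1L, min(5L, n))
    return(moving_average(x, k))
  }
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Savitzky-Golay smoothing for fiducial detection
#'
#' Order-3 Savitzky-Golay filter over roughly 60 ms; unlike a Butterworth
#' low-pass it preserves the position and height of narrow extrema (the
#' dicrotic peak/notch pair in particular), while still suppressing wideband
#' noise before differencing.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param width_s Window width in seconds (default 0.06; forced odd, >= 5
#'   samples).
#' @return Smoothed series.
#' @keywords internal
sgolay_smooth <- function(x, fs, width_s = 0.06) {
  n <- length(x)
  w <- max(5L, round(width_s * fs))
  if (w %% 2 == 0) w <- w + 1L
  if (n <= w + 2) return(x)
  as.numeric(signal::sgolayfilt(x, p = 3, n = w))
}

#' First derivative by central differences
#' @param x Numeric series.
#' @param fs Sampling rate (Hz); result is in units of x per second.
#' @keywords internal
deriv1 <- function(x, fs = 1) {
  n <- length(x)
  stopifnot(n >= 2)
  d <- numeric(n)
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d * fs
}

#' Indices of strict local maxima (earliest wins on flat tops)
#' @keywords internal
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Enforce a minimum index distance between candidate peaks
#'
#' Greedy selection in decreasing height order (earliest wins ties); a
#' candidate closer than `min_dist` samples to an already accepted peak is
#' dropped.
#' @keywords internal
enforce_min_distance <- function(idx, heights, min_dist) {
  if (length(idx) == 0) return(integer(0))
  ord <- order(-heights, idx)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(idx[i] - kept) >= min_dist)) kept <- c(kept, idx[i])
  }
  sort(kept)
}

#' Sub-sample zero-crossing location by linear interpolation
#'
#' Returns the fractional index where `x` crosses zero between samples
#' `i` and `i + 1`.
#' @keywords internal
zero_cross_frac <- function(x, i) {
  denom <- x[i] - x[i + 1]
  if (denom == 0) return(i + 0.5)
  i + x[i] / denom
}

#' Centered moving average with shrinking edge windows
#'
#' @param x Numeric series.
#' @param window Window length in samples; even windows are centred with one
#'   extra trailing sample. `window = 1` is the identity.
#' @return Smoothed series, same length; near the edges the window shrinks to
#'   the available samples.
#' @export
moving_average <- function(x, window = 20) {
  stopifnot(window >= 1)
  n <- length(x)
  if (window == 1 || n == 1) return(x)
  half_l <- floor((window - 1) / 2)
  half_r <- window - 1 - half_l
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Pearson correlation used as normalized cross-correlation at zero lag
#' @keywords internal
ncc <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Normalized cross-correlation maximized over a small lag window
#'
#' A linear convolutional autoencoder recovers the hidden source only up to
#' scale, sign and a small delay; the delay is part of the model's inherent
#' indeterminacy, so source-recovery fidelity is scored as the normalized
#' cross-correlation maximized over lags within `max_lag` samples, on a
#' `step`-sample sub-grid (linear interpolation).
#'
#' @param a,b Series of equal length (`a` is shifted against `b`).
#' @param max_lag Maximum absolute lag in samples (default 5, i.e. 20 ms at
#'   250 Hz).
#' @param step Lag grid step in samples (default 0.25).
#' @return The maximal correlation over the lag grid.
#' @export
ncc_best_lag <- function(a, b, max_lag = 5, step = 0.25) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  lags <- seq(-max_lag, max_lag, by = step)
  core <- (max_lag + 1):(n - max_lag)
  if (length(core) < 8) return(ncc(a, b))
  best <- -Inf
  for (l in lags) {
    as <- stats::approx(seq_len(n), a, xout = core + l)$y
    best <- max(best, stats::cor(as, b[core]))
  }
  best
}

#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Trapezoidal integral with unit spacing
#' @keywords internal
trapz_unit <- function(y) {
  n <- length(y)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2)
}

#' "Same"-size linear convolution matching the encoder index convention
#'
#' `y[t] = sum_f w[f] * x[t + f - offset]` with zero padding outside the
#' support of `x`; `offset = floor(length(w)/2)` aligns the kernel centre.
#' @keywords internal
conv_same <- function(x, w, offset = floor(length(w) / 2)) {
  n <- length(x); f <- length(w)
  xp <- c(numeric(f), x, numeric(f))
  y <- numeric(n)
  for (j in seq_len(f)) {
    y <- y + w[j] * xp[(f + 1 + j - 1 - offset):(f + n + j - 1 - offset)]
  }
  y
}
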