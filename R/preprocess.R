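# Raw Bio-Z to pulsatile dBio-Z: heart-rate estimation, max-slope (MS)
# detection on the first derivative, and DC removal by interpolation between
# the MS anchors of successive beats.

#' Estimate heart rate from the power spectral density
#'
#' Heart rate is the frequency of the most prominent peak of the signal PSD
#' within the physiological band, times 60.
#'
#' @param x One channel of raw Bio-Z (or any pulse) samples.
#' @param fs Sampling rate, Hz.
#' @param band Search band in Hz (default `c(0.6, 3.5)`, i.e. 36-210
#'   beats/min).
#' @return Heart rate in beats/min.
#' @export
estimate_heart_rate <- function(x, fs, band = c(0.6, 3.5)) {
  stopifnot(length(x) > 4, fs > 0)
  if (stats::sd(x) == 0) {
    stop("signal-quality error: flat signal, no spectral peak", call. = FALSE)
  }
  ts_x <- stats::ts(x - mean(x), frequency = fs)
  ps <- stats::spec.pgram(ts_x, spans = c(5, 5), taper = 0.1, detrend = TRUE,
                          plot = FALSE)
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  if (!any(sel)) {
    stop("signal-quality error: no spectral estimate in the heart-rate band",
         call. = FALSE)
  }
  pk <- which.max(ps$spec[sel])
  if (ps$spec[sel][pk] <= 10 * stats::median(ps$spec)) {
    stop("signal-quality error: no prominent peak in the heart-rate band",
         call. = FALSE)
  }
  60 * ps$freq[sel][pk]
}

#' Lower-peak envelope of the first derivative
#'
#' Natural cubic spline through the magnitudes of the derivative's lower
#' peaks (local maxima of the negated derivative), keeping only peaks
#' separated by at least `min_sep` seconds (the larger peak wins within a
#' conflict), evaluated at every sample.
#'
#' @param deriv First-derivative series.
#' @param fs Sampling rate, Hz.
#' @param min_sep Minimum peak separation in seconds (default 0.65).
#' @return Envelope series (positive magnitudes), same length as `deriv`.
#' @export
lower_peak_envelope <- function(deriv, fs, min_sep = 0.65) {
  n <- length(deriv)
  if (n < 2 * min_sep * fs) {
    stop("series too short: length must cover at least two peak separations",
         call. = FALSE)
  }
  neg <- -deriv
  cand <- local_maxima(neg)
  cand <- cand[neg[cand] > 0]
  keep <- enforce_min_distance(cand, neg[cand], min_sep * fs)
  if (length(keep) < 2) {
    stop("envelope error: fewer than two lower peaks", call. = FALSE)
  }
  env <- stats::spline(keep, neg[keep], xout = seq_len(n), method = "natural")$y
  pmax(env, 0)
}

#' Detect per-beat maximum-slope points
#'
#' MS points are the lower peaks of the (lightly smoothed) first derivative
#' of raw Bio-Z, constrained by a minimum peak distance of `0.57 / HR` and a
#' minimum peak height of 35% of the lower-peak envelope.
#'
#' @param x One channel of raw Bio-Z samples.
#' @param fs Sampling rate, Hz.
#' @param hr Heart rate in beats/min (from [estimate_heart_rate()]).
#' @param cutoff Zero-phase low-pass cut-off applied before differencing, Hz.
#' @param min_height_frac Envelope fraction for the height constraint.
#' @param min_dist_frac Beat-period fraction for the distance constraint.
#' @return Increasing integer vector of MS sample indices.
#' @export
detect_max_slope_points <- function(x, fs, hr, cutoff = 15,
                                    min_height_frac = 0.35,
                                    min_dist_frac = 0.57) {
  stopifnot(hr > 0)
  xs <- lowpass_smooth(x, fs, cutoff)
  d1 <- deriv1(xs, fs)
  neg <- -d1
  env <- lower_peak_envelope(d1, fs)
  cand <- local_maxima(neg)
  cand <- cand[neg[cand] > 0 & neg[cand] >= min_height_frac * env[cand]]
  min_dist <- min_dist_frac * (60 / hr) * fs
  ms <- enforce_min_distance(cand, neg[cand], min_dist)
  if (length(ms) == 0) {
    stop("signal-quality error: no max-slope points detected", call. = FALSE)
  }
  ms
}

#' Split raw Bio-Z into DC and pulsatile components
#'
#' The DC (static tissue) component is a monotone piecewise-cubic
#' interpolation through the raw values at the MS anchors, extended flat
#' beyond the first and last anchor; the pulsatile component is the exact
#' remainder, zero at every anchor by construction.
#'
#' @param x One channel of raw Bio-Z samples.
#' @param ms_idx MS anchor indices (at least 2).
#' @return List with `pulsatile` and `dc`, `x == dc + pulsatile` exactly.
#' @export
remove_dc <- function(x, ms_idx) {
  if (length(ms_idx) < 2) {
    stop("cannot interpolate DC from fewer than two max-slope points",
         call. = FALSE)
  }
  f <- stats::splinefun(ms_idx, x[ms_idx], method = "monoH.FC")
  t_eval <- clamp(seq_along(x), min(ms_idx), max(ms_idx))
  dc <- f(t_eval)
  list(pulsatile = x - dc, dc = dc)
}

#' Preprocess a raw recording into pulsatile channels
#'
#' Runs heart-rate estimation (on up to the first `window_min` minutes of the
#' first channel), MS detection and DC removal on every channel.
#'
#' @param record A `bioz_record` (from [synthesize_recording()] or
#'   [read_record()]).
#' @param cutoff Pre-differencing low-pass cut-off, Hz.
#' @param window_min Heart-rate estimation window, minutes (default 2.5).
#' @return Object of class `pulse_channel_set`: `delta` (K x T pulsatile
#'   array, Ohm), `dc` (K x T), `ms` (per-channel MS index lists), `hr`
#'   (beats/min), `p2p` (per-channel median per-beat peak-to-peak), `fs`,
#'   `location_id`.
#' @export
preprocess_record <- function(record, cutoff = 15, window_min = 2.5) {
  stopifnot(inherits(record, "bioz_record"))
  K <- record$K
  fs <- record$fs
  n <- ncol(record$samples)
  n_hr <- min(n, round(window_min * 60 * fs))
  hr <- estimate_heart_rate(record$samples[1, seq_len(n_hr)], fs)
  delta <- matrix(0, K, n)
  dc <- matrix(0, K, n)
  ms <- vector("list", K)
  p2p <- numeric(K)
  for (k in seq_len(K)) {
    ms_k <- detect_max_slope_points(record$samples[k, ], fs, hr, cutoff)
    parts <- remove_dc(record$samples[k, ], ms_k)
    delta[k, ] <- parts$pulsatile
    dc[k, ] <- parts$dc
    ms[[k]] <- ms_k
    if (length(ms_k) >= 2) {
      spans <- cbind(ms_k[-length(ms_k)], ms_k[-1])
      p2p[k] <- stats::median(apply(spans, 1, function(s) {
        diff(range(parts$pulsatile[s[1]:(s[2] - 1)]))
      }))
    }
  }
  structure(list(delta = delta, dc = dc, ms = ms, hr = hr, p2p = p2p,
                 fs = fs, location_id = record$location_id),
            class = "pulse_channel_set")
}

#' @export
print.pulse_channel_set <- function(x, ...) {
  cat(sprintf("<pulse_channel_set> %d channels @ %g Hz, HR %.1f bpm\n",
              nrow(x$delta), x$fs, x$hr))
  cat(sprintf("  median pulse peak-to-peak per channel (mOhm): %s\n",
              paste(sprintf("%.0f", 1000 * x$p2p), collapse = ", ")))
  invisible(x)
}
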