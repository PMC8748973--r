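# Characteristic-point detection and BP feature extraction.
#
# Six points per beat: DIA (diastolic peak), MS (maximum slope), SYS
# (systolic foot) on the main falling edge, then IP (inflection point), with
# DP/DN (dicrotic peak/notch) around it, on the secondary falling edge of the
# reflected wave. All are located from zero crossings of the first and second
# derivatives of the lightly smoothed pulse, with sub-sample resolution by
# linear interpolation between the bracketing samples.

# first d1 zero crossing + -> - at or before index i (fractional), NA if none
zc_down_before <- function(d1, i) {
  j <- i
  while (j >= 2) {
    if (d1[j - 1] >= 0 && d1[j] < 0) return(zero_cross_frac(d1, j - 1))
    j <- j - 1
  }
  NA_real_
}

# first d1 zero crossing - -> + at or after index i (fractional), NA if none
zc_up_after <- function(d1, i) {
  n <- length(d1)
  j <- i
  while (j <= n - 1) {
    if (d1[j] < 0 && d1[j + 1] >= 0) return(zero_cross_frac(d1, j))
    j <- j + 1
  }
  NA_real_
}

#' Detect the six characteristic points of one beat
#'
#' The beat window must contain the full main falling edge (diastolic peak
#' through systolic foot); windows built by [detect_points_record()] start a
#' quarter period before each MS point for this reason. MS is the deepest
#' first-derivative minimum; DIA and SYS are the first-derivative zero
#' crossings immediately before and after it. The dicrotic structure is the
#' most prominent secondary first-derivative minimum after SYS: IP is the
#' second-derivative zero crossing at that minimum, and DP/DN are the
#' first-derivative zero crossings adjacent to IP. An absent dicrotic wave
#' (no qualifying secondary minimum) yields `NA` for DP/IP/DN with
#' `dicrotic_absent = TRUE`, never fabricated points.
#'
#' @param beat Numeric beat window.
#' @param fs Sampling rate, Hz.
#' @param t_ibi Inter-beat interval in seconds (defaults to the window
#'   length; pass the MS-to-MS period when known).
#' @param smooth_width_s Width of the Savitzky-Golay pre-derivative
#'   smoother, seconds.
#' @param min_dicrotic_frac Minimum depth of the secondary derivative
#'   minimum, as a fraction of the MS derivative depth, below which the
#'   dicrotic structure is declared absent.
#' @return A one-row data.frame with sub-sample times (s, relative to the
#'   window start), amplitudes, `t_ibi`, `a_sys` (foot-to-peak amplitude),
#'   `dicrotic_absent` and `valid`.
#' @export
detect_characteristic_points <- function(beat, fs, t_ibi = NULL,
                                         smooth_width_s = 0.06,
                                         min_dicrotic_frac = 0.02) {
  n <- length(beat)
  empty <- data.frame(valid = FALSE, dicrotic_absent = NA,
                      t_dia = NA_real_, t_ms = NA_real_, t_sys = NA_real_,
                      t_dp = NA_real_, t_ip = NA_real_, t_dn = NA_real_,
                      a_dia = NA_real_, a_ms = NA_real_, a_sys_pt = NA_real_,
                      a_dp = NA_real_, a_ip = NA_real_, a_dn = NA_real_,
                      t_ibi = NA_real_, a_sys = NA_real_)
  if (n < 8 || diff(range(beat)) == 0) return(empty)
  if (is.null(t_ibi)) t_ibi <- n / fs
  x <- sgolay_smooth(beat, fs, smooth_width_s)
  d1 <- deriv1(x, fs)
  ms_i <- which.min(d1)
  if (d1[ms_i] >= 0 || ms_i < 2 || ms_i > n - 2) return(empty)
  dia_f <- zc_down_before(d1, ms_i)
  sys_f <- zc_up_after(d1, ms_i)
  if (is.na(dia_f) || is.na(sys_f)) return(empty)
  amp_at <- function(t) stats::approx(seq_len(n), x, xout = t)$y
  ms_f <- ms_i # deepest-minimum sample; sub-sample refinement via d2 crossing
  d2 <- deriv1(d1, fs)
  if (ms_i >= 2 && ms_i <= n - 1 && d2[ms_i - 1] < 0 && d2[ms_i] >= 0) {
    ms_f <- zero_cross_frac(d2, ms_i - 1)
  } else if (ms_i <= n - 1 && d2[ms_i] < 0 && d2[ms_i + 1] >= 0) {
    ms_f <- zero_cross_frac(d2, ms_i)
  }
  # secondary falling edge: most prominent d1 local minimum after SYS
  sys_i <- ceiling(sys_f)
  dp_f <- ip_f <- dn_f <- NA_real_
  cand <- local_maxima(-d1)
  cand <- cand[cand > sys_i + 1 & cand < n - 1 &
                 d1[cand] < -min_dicrotic_frac * abs(d1[ms_i])]
  if (length(cand)) {
    ip_i <- cand[which.min(d1[cand])]
    ip_f <- ip_i
    if (d2[ip_i - 1] < 0 && d2[ip_i] >= 0) {
      ip_f <- zero_cross_frac(d2, ip_i - 1)
    } else if (ip_i <= n - 1 && d2[ip_i] < 0 && d2[ip_i + 1] >= 0) {
      ip_f <- zero_cross_frac(d2, ip_i)
    }
    dp_f <- zc_down_before(d1, ip_i)
    dn_f <- zc_up_after(d1, ip_i)
    if (!is.na(dp_f) && dp_f <= sys_f) dp_f <- NA_real_
    if (is.na(dp_f) || is.na(dn_f)) dp_f <- ip_f <- dn_f <- NA_real_
  }
  a_dia <- amp_at(dia_f); a_sys_pt <- amp_at(sys_f)
  a_sys <- a_dia - a_sys_pt
  if (!is.finite(a_sys) || a_sys <= 0) return(empty)
  data.frame(valid = TRUE, dicrotic_absent = is.na(dp_f),
             t_dia = (dia_f - 1) / fs, t_ms = (ms_f - 1) / fs,
             t_sys = (sys_f - 1) / fs,
             t_dp = (dp_f - 1) / fs, t_ip = (ip_f - 1) / fs,
             t_dn = (dn_f - 1) / fs,
             a_dia = a_dia, a_ms = amp_at(ms_f), a_sys_pt = a_sys_pt,
             a_dp = if (is.na(dp_f)) NA_real_ else amp_at(dp_f),
             a_ip = if (is.na(ip_f)) NA_real_ else amp_at(ip_f),
             a_dn = if (is.na(dn_f)) NA_real_ else amp_at(dn_f),
             t_ibi = t_ibi, a_sys = a_sys)
}

#' Detect characteristic points for every beat of a pulse series
#'
#' Builds one window per beat, starting a quarter of the inter-beat interval
#' before each MS anchor (so the diastolic peak preceding the edge is
#' inside), and runs [detect_characteristic_points()] on each. Edge beats
#' whose window would leave the series are marked invalid.
#'
#' @param series Pulse series (e.g. `reconstructed_pulse$series` or one
#'   channel of `pulse_channel_set$delta`).
#' @param fs Sampling rate, Hz.
#' @param spans n x 2 matrix of beat spans `[MS_i, MS_{i+1})` in the
#'   coordinates of `series`' parent record; `origin` gives the global index
#'   of `series[1]`.
#' @param origin Global sample index of the first element of `series`.
#' @return A data.frame (one row per beat) of characteristic points, with
#'   `win_start` (window offset within `series`) and `beat` columns.
#' @export
detect_points_record <- function(series, fs, spans, origin = spans[1, 1]) {
  n_beats <- nrow(spans)
  out <- vector("list", n_beats)
  len <- length(series)
  for (b in seq_len(n_beats)) {
    t_n <- spans[b, 2] - spans[b, 1]
    off <- round(0.25 * t_n)
    w0 <- spans[b, 1] - origin + 1 - off
    w1 <- spans[b, 2] - origin - off
    if (w0 < 1 || w1 > len) {
      row <- detect_characteristic_points(numeric(0), fs)
    } else {
      row <- detect_characteristic_points(series[w0:w1], fs, t_ibi = t_n / fs)
    }
    row$win_start <- w0
    row$beat <- b
    out[[b]] <- row
  }
  do.call(rbind, out)
}

#' Time features: DIA-to-point intervals over the inter-beat interval
#' @param points One row of characteristic points.
#' @return Named numeric: `t_dia_ms`, `t_dia_sys`, `t_dia_ip` (each in
#'   `[0, 1]`; `t_dia_ip` is `NA` when the inflection point is absent).
#' @export
extract_time_features <- function(points) {
  c(t_dia_ms = (points$t_ms - points$t_dia) / points$t_ibi,
    t_dia_sys = (points$t_sys - points$t_dia) / points$t_ibi,
    t_dia_ip = (points$t_ip - points$t_dia) / points$t_ibi)
}

#' Amplitude features: DIA-to-point drops over the foot-to-peak amplitude
#' @param points One row of characteristic points.
#' @return Named numeric: `a_dia_ms`, `a_dia_ip`.
#' @export
extract_amplitude_features <- function(points) {
  c(a_dia_ms = (points$a_dia - points$a_ms) / points$a_sys,
    a_dia_ip = (points$a_dia - points$a_ip) / points$a_sys)
}

#' Area features: partial areas from DIA, over the full pulse area
#'
#' Trapezoidal areas of the min-shifted beat from the DIA sample to the MS,
#' SYS and IP samples, divided by the area over the full window from DIA on.
#'
#' @param beat The beat window the points were detected in.
#' @param points One row of characteristic points.
#' @param fs Sampling rate, Hz.
#' @return Named numeric: `ar_dia_ms`, `ar_dia_sys`, `ar_dia_ip`, each in
#'   `[0, 1]` and monotone in that order.
#' @export
extract_area_features <- function(beat, points, fs) {
  n <- length(beat)
  base <- beat - min(beat)
  i_dia <- clamp(round(points$t_dia * fs) + 1, 1, n)
  full <- trapz_unit(base[i_dia:n])
  if (full <= 0) {
    return(c(ar_dia_ms = NA_real_, ar_dia_sys = NA_real_, ar_dia_ip = NA_real_))
  }
  part <- function(t_pt) {
    if (is.na(t_pt)) return(NA_real_)
    i <- clamp(round(t_pt * fs) + 1, 1, n)
    trapz_unit(base[i_dia:i]) / full
  }
  c(ar_dia_ms = part(points$t_ms),
    ar_dia_sys = part(points$t_sys),
    ar_dia_ip = part(points$t_ip))
}

#' Dicrotic features: peak-to-notch amplitude and time
#' @param points One row of characteristic points.
#' @return Named numeric: `d_amp = (A_DP - A_DN)/A_SYS`,
#'   `d_time = (t_DN - t_DP)/T_IBI`; `NA` when the dicrotic pair is absent.
#' @export
extract_dicrotic_features <- function(points) {
  c(d_amp = (points$a_dp - points$a_dn) / points$a_sys,
    d_time = (points$t_dn - points$t_dp) / points$t_ibi)
}

#' Amplitude-histogram features: five equal bins of the normalized pulse
#'
#' The beat is amplitude-normalized to `[0, 1]` and the fraction of samples
#' falling in each of the five equal intervals is returned (fractions, so
#' the feature does not depend on the beat length).
#'
#' @param beat Numeric beat window.
#' @return Named numeric `h1..h5`, summing to 1.
#' @export
extract_histogram_features <- function(beat) {
  rng <- range(beat)
  if (diff(rng) == 0) stop("flat beat rejected for histogram", call. = FALSE)
  y <- (beat - rng[1]) / diff(rng)
  edges <- seq(0, 1, by = 0.2)
  h <- numeric(5)
  for (i in 1:4) h[i] <- mean(y >= edges[i] & y < edges[i + 1])
  h[5] <- mean(y >= edges[5])
  names(h) <- paste0("h", 1:5)
  h
}

#' Extract the full 15-feature table for a pulse series
#'
#' Runs point detection beat-by-beat and assembles the three time, two
#' amplitude, three area, two dicrotic and five histogram features per beat.
#'
#' @inheritParams detect_points_record
#' @return A data.frame with one row per beat: `beat`, `valid`,
#'   `dicrotic_absent`, and the 15 feature columns.
#' @export
extract_beat_features <- function(series, fs, spans, origin = spans[1, 1]) {
  pts <- detect_points_record(series, fs, spans, origin)
  feat_names <- c("t_dia_ms", "t_dia_sys", "t_dia_ip",
                  "a_dia_ms", "a_dia_ip",
                  "ar_dia_ms", "ar_dia_sys", "ar_dia_ip",
                  "d_amp", "d_time", paste0("h", 1:5))
  out <- matrix(NA_real_, nrow(pts), length(feat_names),
                dimnames = list(NULL, feat_names))
  len <- length(series)
  for (b in seq_len(nrow(pts))) {
    p <- pts[b, ]
    if (!isTRUE(p$valid)) next
    t_n <- spans[b, 2] - spans[b, 1]
    w0 <- p$win_start
    beat <- series[w0:min(len, w0 + t_n - 1)]
    out[b, 1:3] <- extract_time_features(p)
    out[b, 4:5] <- extract_amplitude_features(p)
    out[b, 6:8] <- extract_area_features(beat, p, fs)
    out[b, 9:10] <- extract_dicrotic_features(p)
    out[b, 11:15] <- extract_histogram_features(beat)
  }
  cbind(pts[, c("beat", "valid", "dicrotic_absent")], as.data.frame(out))
}

#' Impute missing dicrotic/inflection features by the column median
#'
#' Beats with an absent dicrotic wave carry `NA` in `t_dia_ip`, `a_dia_ip`,
#' `ar_dia_ip`, `d_amp` and `d_time`; before regression these are imputed by
#' the per-subject median of valid beats (a column with no valid values
#' imputes to 0).
#'
#' @param features Feature data.frame from [extract_beat_features()].
#' @return The data.frame with feature `NA`s filled in.
#' @export
impute_features <- function(features) {
  cols <- setdiff(names(features), c("beat", "valid", "dicrotic_absent"))
  for (cn in cols) {
    v <- features[[cn]]
    if (anyNA(v)) {
      med <- stats::median(v, na.rm = TRUE)
      if (!is.finite(med)) med <- 0
      v[is.na(v)] <- med
      features[[cn]] <- v
    }
  }
  features
}
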