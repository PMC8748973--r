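# Beat segmentation and normalization: the K-channel pulsatile signal is cut
# into heartbeats on a common beat grid (the reference channel's MS points),
# each beat is resampled to L samples and scaled to unit peak-to-peak, and
# overlapping N-beat segments are assembled for autoencoder training.

#' Index of the reference channel (highest pulse amplitude)
#'
#' Beat boundaries are taken from a single reference channel and applied to
#' all channels so that the N x K x L segment array shares one beat grid;
#' the channel with the largest median per-beat peak-to-peak is used.
#'
#' @param pulse_set A `pulse_channel_set`.
#' @return Integer channel index.
#' @export
reference_channel <- function(pulse_set) {
  stopifnot(inherits(pulse_set, "pulse_channel_set"))
  which.max(pulse_set$p2p)
}

#' Segment pulsatile channels into beats
#'
#' Beat `i` spans `[MS_i, MS_{i+1})` of the reference channel's MS points,
#' applied to every channel.
#'
#' @param pulse_set A `pulse_channel_set`.
#' @param ms_ref Reference MS indices (default: the reference channel's).
#' @return List with `spans` (n x 2 matrix of half-open sample spans) and
#'   `beats` (list of K x len matrices).
#' @export
segment_beats <- function(pulse_set, ms_ref = NULL) {
  stopifnot(inherits(pulse_set, "pulse_channel_set"))
  if (is.null(ms_ref)) ms_ref <- pulse_set$ms[[reference_channel(pulse_set)]]
  if (length(ms_ref) < 2) {
    return(list(spans = matrix(integer(0), 0, 2), beats = list()))
  }
  spans <- cbind(start = ms_ref[-length(ms_ref)], end = ms_ref[-1])
  beats <- lapply(seq_len(nrow(spans)), function(i) {
    pulse_set$delta[, spans[i, 1]:(spans[i, 2] - 1), drop = FALSE]
  })
  list(spans = spans, beats = beats)
}

#' Normalize one beat to L samples and unit peak-to-peak
#'
#' Linear interpolation at `L` equally spaced time points spanning the beat,
#' then division of each channel by its peak-to-peak amplitude.
#'
#' @param beat K x len matrix (or a plain vector for K = 1).
#' @param L Target number of samples.
#' @return List with `data` (K x L), `scales` (per-channel peak-to-peak) —
#'   or an error for beats shorter than 4 samples or with a flat channel.
#' @export
normalize_beat <- function(beat, L) {
  if (is.vector(beat)) beat <- matrix(beat, nrow = 1)
  len <- ncol(beat)
  if (len < 4) stop("beat too short to resample", call. = FALSE)
  xout <- seq(1, len, length.out = L)
  out <- matrix(0, nrow(beat), L)
  scales <- numeric(nrow(beat))
  for (k in seq_len(nrow(beat))) {
    y <- stats::approx(seq_len(len), beat[k, ], xout = xout)$y
    s <- diff(range(y))
    if (s == 0) stop("flat beat rejected (zero peak-to-peak)", call. = FALSE)
    out[k, ] <- y / s
    scales[k] <- s
  }
  list(data = out, scales = scales)
}

#' Invert beat normalization (round trip helper)
#' @param norm K x L normalized beat.
#' @param scales Per-channel peak-to-peak scales.
#' @param len Original beat length in samples.
#' @return K x len matrix.
#' @export
denormalize_beat <- function(norm, scales, len) {
  if (is.vector(norm)) norm <- matrix(norm, nrow = 1)
  L <- ncol(norm)
  out <- matrix(0, nrow(norm), len)
  xout <- seq(1, L, length.out = len)
  for (k in seq_len(nrow(norm))) {
    out[k, ] <- stats::approx(seq_len(L), norm[k, ] * scales[k], xout = xout)$y
  }
  out
}

#' Build the normalized beat tensor
#'
#' @param pulse_set A `pulse_channel_set`.
#' @param L Samples per normalized beat (default 64).
#' @param ms_ref Optional explicit beat grid.
#' @return Object of class `beat_tensor`: `data` (N_total x K x L array),
#'   `spans`, `scales` (N_total x K), `fs`, plus the original-rate `delta`
#'   matrix needed to reconstruct at full resolution. Beats that fail
#'   normalization are dropped (their spans recorded in `dropped`).
#' @export
build_beat_tensor <- function(pulse_set, L = 64, ms_ref = NULL) {
  seg <- segment_beats(pulse_set, ms_ref)
  n <- nrow(seg$spans)
  if (n == 0) stop("no beats to assemble (need at least 2 MS points)", call. = FALSE)
  K <- nrow(pulse_set$delta)
  data <- array(NA_real_, c(n, K, L))
  scales <- matrix(NA_real_, n, K)
  ok <- logical(n)
  for (i in seq_len(n)) {
    nb <- tryCatch(normalize_beat(seg$beats[[i]], L), error = function(e) NULL)
    if (!is.null(nb)) {
      data[i, , ] <- nb$data
      scales[i, ] <- nb$scales
      ok[i] <- TRUE
    }
  }
  structure(list(data = data[ok, , , drop = FALSE],
                 spans = seg$spans[ok, , drop = FALSE],
                 scales = scales[ok, , drop = FALSE],
                 dropped = seg$spans[!ok, , drop = FALSE],
                 delta = pulse_set$delta, fs = pulse_set$fs, L = L, K = K),
            class = "beat_tensor")
}

#' Assemble overlapping N-beat training segments
#'
#' Each channel's normalized beats are concatenated into one stream of
#' `N_total * L` samples; windows of `N * L` samples advance by
#' `round(hop_fraction * L)` samples, and each window is reshaped to
#' N beats x K channels x L samples.
#'
#' @param tensor A `beat_tensor`.
#' @param N Beats per segment (default 8).
#' @param hop_fraction Hop as a fraction of the normalized beat length
#'   (default 0.1).
#' @return Object of class `segment_batch`: `segments` (array
#'   `(N*K) x L x S`, row index `j = (n-1)*K + k`), `hop` (samples), and the
#'   `(N, K, L)` geometry. `S = floor((N_total*L - N*L)/hop) + 1`.
#' @export
build_segments <- function(tensor, N = 8, hop_fraction = 0.1) {
  stopifnot(inherits(tensor, "beat_tensor"))
  n_total <- dim(tensor$data)[1]
  K <- dim(tensor$data)[2]
  L <- dim(tensor$data)[3]
  if (n_total < N) {
    stop(sprintf("need at least N = %d beats, have %d", N, n_total), call. = FALSE)
  }
  hop <- max(1L, round(hop_fraction * L))
  S <- floor((n_total * L - N * L) / hop) + 1L
  # per-channel concatenated streams: K x (n_total * L)
  streams <- matrix(0, K, n_total * L)
  for (k in seq_len(K)) {
    streams[k, ] <- as.vector(t(tensor$data[, k, ]))
  }
  segs <- array(0, c(N * K, L, S))
  for (s in seq_len(S)) {
    a <- (s - 1L) * hop
    for (n_i in seq_len(N)) {
      cols <- (a + (n_i - 1L) * L + 1L):(a + n_i * L)
      segs[((n_i - 1L) * K + 1L):(n_i * K), , s] <- streams[, cols]
    }
  }
  structure(list(segments = segs, hop = hop, N = N, K = K, L = L,
                 n_total = n_total),
            class = "segment_batch")
}
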