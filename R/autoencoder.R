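# Linear convolutional autoencoder for arterial pulse reconstruction.
#
# Encoder: one 3-D convolution window of size N x K x F (stride 1 along the
# normalized-time axis, zero padding), linear activation, zero bias; its
# output, a length-L code, is the estimate of the hidden arterial pulse for
# the segment. Decoder: N*K independent 1-D FIR kernels of length F (linear,
# zero bias) mapping the code back to every beat/channel slice. Total
# trainable parameters: exactly 2*N*K*F. Training minimizes mean squared
# reconstruction error with Adam. Because the decoder must re-synthesize
# every channel from the code through only F taps, the code is pushed
# towards a delay/scale version of the common underlying pulse.

#' Autoencoder configuration
#'
#' @param N Beats per segment.
#' @param K Channels.
#' @param F Filter width in normalized-time samples (`1 <= F <= L`).
#' @param L Normalized beat length.
#' @param lr Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param batch Mini-batch size.
#' @param patience Plateau patience (epochs without relative improvement
#'   better than `tol`).
#' @param tol Relative loss-improvement tolerance defining a plateau.
#' @param lr_decay Factor applied to the learning rate at each plateau.
#' @param max_lr_drops Number of plateau-triggered learning-rate reductions
#'   before training stops.
#' @param max_segments Cap on training segments; at a hop of `0.1 L`
#'   consecutive segments overlap almost completely, so an evenly spaced
#'   subset carries the same information at a fraction of the cost.
#' @param init_sd SD of the random weight initialization.
#' @param seed RNG seed for initialization and batch shuffling.
#' @return Object of class `ae_config`.
#' @export
ae_config <- function(N = 8, K = 6, F = 9, L = 64, lr = 3e-3, epochs = 80,
                      batch = 64, patience = 10, tol = 1e-3,
                      lr_decay = 0.3, max_lr_drops = 2,
                      max_segments = 600, init_sd = 0.05, seed = 1) {
  stopifnot(N >= 1, K >= 1, F >= 1, F <= L, lr > 0, epochs >= 1, batch >= 1,
            lr_decay > 0, lr_decay < 1, max_lr_drops >= 0)
  structure(list(N = N, K = K, F = F, L = L, lr = lr, epochs = epochs,
                 batch = batch, patience = patience, tol = tol,
                 lr_decay = lr_decay, max_lr_drops = max_lr_drops,
                 max_segments = max_segments, init_sd = init_sd, seed = seed),
            class = "ae_config")
}

#' Initialize autoencoder weights
#'
#' Seeded small random encoder/decoder kernels; biases are identically zero
#' and are not trainable parameters.
#'
#' @param config An [ae_config()].
#' @return Object of class `ae_weights` with `encoder` (`(N*K) x F` matrix,
#'   row `j = (n-1)*K + k`), `decoder` (same layout), `biases = 0`, and the
#'   geometry.
#' @export
init_autoencoder <- function(config) {
  stopifnot(inherits(config, "ae_config"))
  j <- config$N * config$K
  with_seed(config$seed, {
    W <- matrix(stats::rnorm(j * config$F, 0, config$init_sd), j, config$F)
    D <- matrix(stats::rnorm(j * config$F, 0, config$init_sd), j, config$F)
  })
  structure(list(encoder = W, decoder = D, biases = 0,
                 N = config$N, K = config$K, F = config$F, L = config$L),
            class = "ae_weights")
}

#' Number of trainable parameters
#' @param weights An `ae_weights`.
#' @return `2 * N * K * F`.
#' @export
ae_param_count <- function(weights) {
  length(weights$encoder) + length(weights$decoder)
}

# coerce an N x K x L array (or (N*K) x L matrix) to the internal matrix form
as_segment_matrix <- function(segment, N, K, L) {
  if (is.matrix(segment)) {
    stopifnot(nrow(segment) == N * K, ncol(segment) == L)
    return(segment)
  }
  stopifnot(length(dim(segment)) == 3, all(dim(segment) == c(N, K, L)))
  m <- matrix(0, N * K, L)
  for (n_i in seq_len(N)) m[((n_i - 1) * K + 1):(n_i * K), ] <- segment[n_i, , ]
  m
}

#' Encode a segment to its length-L code
#'
#' `code[t] = sum_{n,k,f} encoder[n,k,f] * segment[n,k,t + f - floor(F/2)]`
#' with zero padding outside the segment; linear, no bias.
#'
#' @param segment N x K x L array or `(N*K) x L` matrix.
#' @param weights An `ae_weights`.
#' @return Numeric code of length L.
#' @export
encode_segment <- function(segment, weights) {
  m <- as_segment_matrix(segment, weights$N, weights$K, weights$L)
  L <- weights$L; F <- weights$F; o <- floor(F / 2)
  mp <- cbind(matrix(0, nrow(m), F), m, matrix(0, nrow(m), F))
  code <- numeric(L)
  for (f in seq_len(F)) {
    cols <- (f - o + F):(L + f - 1 - o + F)
    code <- code + colSums(weights$encoder[, f] * mp[, cols, drop = FALSE])
  }
  code
}

#' Decode a code to the segment reconstruction
#'
#' `recon[n,k,t] = sum_f decoder[n,k,f] * code[t + f - floor(F/2)]`, zero
#' padded; linear, no bias.
#'
#' @param code Numeric code of length L.
#' @param weights An `ae_weights`.
#' @return `(N*K) x L` reconstruction matrix (row `j = (n-1)*K + k`).
#' @export
decode_code <- function(code, weights) {
  L <- weights$L; F <- weights$F; o <- floor(F / 2)
  cp <- c(numeric(F), code, numeric(F))
  recon <- matrix(0, nrow(weights$decoder), L)
  for (f in seq_len(F)) {
    cols <- (f - o + F):(L + f - 1 - o + F)
    recon <- recon + outer(weights$decoder[, f], cp[cols])
  }
  recon
}

# forward + gradients for one mini-batch; A is j x L x B.
# The convolutions are unrolled im2col-style into two patch matrices so the
# whole pass runs as dense BLAS products: PA rows stack the F shifted copies
# of the padded input, PE the reverse-shifted copies of the padded error.
ae_batch_grad <- function(A, W, D, F, o) {
  j <- dim(A)[1]; L <- dim(A)[2]; B <- dim(A)[3]
  Lp <- L + 2 * F
  Ap <- array(0, c(j, Lp, B))
  Ap[, (F + 1):(F + L), ] <- A
  PA <- matrix(0, j * F, L * B)
  for (f in seq_len(F)) {
    cols <- (f - o + F):(L + f - 1 - o + F)
    PA[((f - 1) * j + 1):(f * j), ] <- matrix(Ap[, cols, ], j, L * B)
  }
  # encode: code[t] = sum_{j,f} W[j,f] A[j, t+f-1-o]
  Cv <- crossprod(PA, as.vector(W))              # (L*B) x 1
  # decode through F shifted copies of the padded code
  Cp <- matrix(0, Lp, B)
  Cp[(F + 1):(F + L), ] <- Cv
  CP <- matrix(0, F, L * B)
  for (f in seq_len(F)) {
    cols <- (f - o + F):(L + f - 1 - o + F)
    CP[f, ] <- Cp[cols, ]
  }
  Rm <- D %*% CP                                  # j x (L*B)
  E <- Rm - matrix(A, j, L * B)
  loss <- mean(E^2)
  dR <- (2 / length(E)) * E
  gD <- tcrossprod(dR, CP)                        # j x F
  # gradient wrt the code: dC[t] = sum_{j,f} D[j,f] dR[j, t-f+1+o]
  dRp <- array(0, c(j, Lp, B))
  dRp[, (F + 1):(F + L), ] <- dR
  PE <- matrix(0, j * F, L * B)
  for (f in seq_len(F)) {
    cols <- (2 - f + o + F):(L + 1 - f + o + F)
    PE[((f - 1) * j + 1):(f * j), ] <- matrix(dRp[, cols, ], j, L * B)
  }
  dCv <- crossprod(PE, as.vector(D))              # (L*B) x 1
  gW <- matrix(PA %*% dCv, j, F)
  list(loss = loss, gW = gW, gD = gD)
}

#' Train the autoencoder
#'
#' Adam on the mean squared reconstruction error over mini-batches of
#' segments; biases stay identically zero (they are not parameters). When the
#' epoch loss plateaus (no relative improvement of `tol` for `patience`
#' epochs) the learning rate is reduced by `lr_decay`, up to `max_lr_drops`
#' times; the next plateau stops training.
#'
#' @param batch A `segment_batch` from [build_segments()].
#' @param config An [ae_config()] whose geometry matches the batch.
#' @return An `ae_weights` with attribute `loss_history` (per-epoch mean
#'   training loss).
#' @export
train_autoencoder <- function(batch, config) {
  stopifnot(inherits(batch, "segment_batch"), inherits(config, "ae_config"),
            batch$N == config$N, batch$K == config$K, batch$L == config$L)
  segs <- batch$segments
  S <- dim(segs)[3]
  if (S < 1) stop("need at least one training segment", call. = FALSE)
  if (S > config$max_segments) {
    keep <- unique(round(seq(1, S, length.out = config$max_segments)))
    segs <- segs[, , keep, drop = FALSE]
    S <- dim(segs)[3]
  }
  weights <- init_autoencoder(config)
  W <- weights$encoder; D <- weights$decoder
  F <- config$F; o <- floor(F / 2)
  lr <- config$lr; drops <- 0
  mW <- vW <- matrix(0, nrow(W), ncol(W))
  mD <- vD <- matrix(0, nrow(D), ncol(D))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  history <- numeric(0)
  best <- Inf; best_epoch <- 0
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(S)
      starts <- seq(1, S, by = config$batch)
      losses <- numeric(length(starts))
      for (i in seq_along(starts)) {
        idx <- ord[starts[i]:min(starts[i] + config$batch - 1, S)]
        g <- ae_batch_grad(segs[, , idx, drop = FALSE], W, D, F, o)
        if (!is.finite(g$loss)) {
          stop("training diverged (non-finite loss); lower lr or check inputs",
               call. = FALSE)
        }
        losses[i] <- g$loss
        step <- step + 1
        mW <- b1 * mW + (1 - b1) * g$gW
        vW <- b2 * vW + (1 - b2) * g$gW^2
        mD <- b1 * mD + (1 - b1) * g$gD
        vD <- b2 * vD + (1 - b2) * g$gD^2
        corr <- sqrt(1 - b2^step) / (1 - b1^step)
        W <- W - lr * corr * mW / (sqrt(vW) + eps)
        D <- D - lr * corr * mD / (sqrt(vD) + eps)
      }
      history <- c(history, mean(losses))
      if (history[epoch] < best * (1 - config$tol)) {
        best <- history[epoch]
        best_epoch <- epoch
      } else if (epoch - best_epoch >= config$patience) {
        if (drops >= config$max_lr_drops) break
        lr <- lr * config$lr_decay  # descend further on the plateau
        drops <- drops + 1
        best_epoch <- epoch
      }
    }
  })
  weights$encoder <- W
  weights$decoder <- D
  attr(weights, "loss_history") <- history
  weights
}

#' Reconstruct the arterial pulse at the original sampling rate
#'
#' The trained encoder kernels, defined on the F-tap normalized-time grid,
#' are linearly interpolated onto each beat's original-rate tap grid and
#' applied to the original-rate, amplitude-normalized K-channel beat stream.
#' Each beat is reconstructed from the N-beat window centred on it (clamped
#' at the record edges); contributions from neighbouring beats are evaluated
#' on their own time grids and phase-resampled onto the target beat. The
#' concatenated output is re-signed so its main intra-beat edge is falling
#' (the measurement convention) and re-scaled to unit peak-to-peak per beat
#' — the latent code of a linear autoencoder is only defined up to
#' scale and sign.
#'
#' @param weights Trained `ae_weights`.
#' @param tensor The `beat_tensor` the segments were built from (provides the
#'   original-rate pulsatile data and per-beat scales).
#' @return Object of class `reconstructed_pulse`: `series` (one channel at
#'   the original rate, spanning all analyzed beats), `beat_spans`, `fs`.
#' @export
reconstruct_arterial_pulse <- function(weights, tensor) {
  stopifnot(inherits(weights, "ae_weights"), inherits(tensor, "beat_tensor"))
  n_total <- nrow(tensor$spans)
  N <- weights$N; K <- weights$K; F <- weights$F; L <- weights$L
  if (n_total < N) stop("fewer beats than the segment depth N", call. = FALSE)
  tap_grid <- seq(0, 1, length.out = F)
  out_beats <- vector("list", n_total)
  n_c <- ceiling(N / 2)
  for (b in seq_len(n_total)) {
    q0 <- clamp(b - n_c + 1, 1, n_total - N + 1)
    len_b <- tensor$spans[b, 2] - tensor$spans[b, 1]
    acc <- numeric(len_b)
    for (n_i in seq_len(N)) {
      q <- q0 + n_i - 1
      len_q <- tensor$spans[q, 2] - tensor$spans[q, 1]
      f_up <- max(2L, round(F * len_q / L))
      o_up <- floor(f_up / 2)
      up_grid <- seq(0, 1, length.out = f_up)
      cols <- tensor$spans[q, 1]:(tensor$spans[q, 2] - 1)
      for (k in seq_len(K)) {
        taps <- stats::approx(tap_grid, weights$encoder[(n_i - 1) * K + k, ],
                              xout = up_grid)$y * (F / f_up)
        xq <- tensor$delta[k, cols] / tensor$scales[q, k]
        contrib <- conv_same(xq, taps, o_up)
        if (len_q != len_b) {
          contrib <- stats::approx(seq(0, 1, length.out = len_q), contrib,
                                   xout = seq(0, 1, length.out = len_b))$y
        }
        acc <- acc + contrib
      }
    }
    out_beats[[b]] <- acc
  }
  # global sign: the dominant intra-beat edge must fall
  fall <- vapply(out_beats, function(y) {
    d <- diff(y); abs(min(d)) - abs(max(d))
  }, numeric(1))
  sgn <- if (stats::median(fall) < 0) -1 else 1
  series <- unlist(lapply(out_beats, function(y) {
    y <- sgn * y
    p <- diff(range(y))
    if (p > 0) (y - mean(y)) / p else y
  }), use.names = FALSE)
  structure(list(series = series, beat_spans = tensor$spans, fs = tensor$fs),
            class = "reconstructed_pulse")
}

#' Model label for a sensing location
#'
#' Four independent autoencoders are kept per subject, one per sensing
#' location (`AE1`-`AE4` for `POS1`, `POS2`, `POS3`, `ReAttach`).
#' @param location_id Location string.
#' @return Model label.
#' @export
ae_model_label <- function(location_id) {
  switch(location_id,
         POS1 = "AE1", POS2 = "AE2", POS3 = "AE3", ReAttach = "AE4",
         stop("unknown location: ", location_id, call. = FALSE))
}
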