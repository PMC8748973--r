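# Linear convolutional autoencoder: architecture contract, linear-algebra
# identities, gradient correctness, training behaviour, reconstruction.

test_that("parameter count is exactly 2 N K F and biases are zero", {
  for (N in c(1, 4, 8)) for (K in c(1, 6)) for (F in c(1, 5, 9)) {
    w <- init_autoencoder(ae_config(N = N, K = K, F = F, L = 16, seed = 1))
    expect_equal(ae_param_count(w), 2 * N * K * F)
    expect_identical(w$biases, 0)
  }
  # identical seeds give identical weights
  w1 <- init_autoencoder(ae_config(seed = 5))
  w2 <- init_autoencoder(ae_config(seed = 5))
  expect_identical(w1, w2)
})

test_that("encode and decode satisfy their linear identities", {
  cfg <- ae_config(N = 2, K = 2, F = 1, L = 8, seed = 1)
  w <- init_autoencoder(cfg)
  set.seed(3)
  seg <- array(rnorm(2 * 2 * 8), c(2, 2, 8))
  # zero encoder -> zero code
  w0 <- w; w0$encoder[, ] <- 0
  expect_equal(encode_segment(seg, w0), rep(0, 8))
  # F = 1 delta at one (n, k) picks out that slice
  wd <- w; wd$encoder[, ] <- 0; wd$encoder[3, 1] <- 1  # (n=2, k=1)
  expect_equal(encode_segment(seg, wd), seg[2, 1, ])
  # homogeneity
  expect_equal(encode_segment(2 * seg, w), 2 * encode_segment(seg, w))
  # decoder: zero code -> zero reconstruction; delta kernels copy the code
  cfg3 <- ae_config(N = 1, K = 2, F = 3, L = 8, seed = 1)
  w3 <- init_autoencoder(cfg3)
  code <- rnorm(8)
  expect_equal(decode_code(numeric(8), w3), matrix(0, 2, 8))
  wd3 <- w3; wd3$decoder[, ] <- 0; wd3$decoder[, 2] <- 1
  r <- decode_code(code, wd3)
  expect_equal(r[1, ], code)
  expect_equal(r[2, ], code)
  expect_equal(decode_code(2 * code, w3), 2 * decode_code(code, w3))
})

test_that("encoder reduces to a direct convolution for N = K = 1, F = L", {
  cfg <- ae_config(N = 1, K = 1, F = 8, L = 8, seed = 2)
  w <- init_autoencoder(cfg)
  set.seed(4)
  x <- rnorm(8)
  code <- encode_segment(matrix(x, 1, 8), w)
  o <- floor(8 / 2)
  brute <- vapply(1:8, function(t) {
    s <- 0
    for (f in 1:8) {
      idx <- t + f - 1 - o
      if (idx >= 1 && idx <= 8) s <- s + w$encoder[1, f] * x[idx]
    }
    s
  }, numeric(1))
  expect_equal(code, brute, tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- ae_config(N = 2, K = 3, F = 5, L = 16, seed = 7)
  w <- init_autoencoder(cfg)
  set.seed(42)
  A <- array(rnorm(2 * 3 * 16 * 4), c(6, 16, 4))
  o <- floor(cfg$F / 2)
  g <- biozbp:::ae_batch_grad(A, w$encoder, w$decoder, cfg$F, o)
  eps <- 1e-6
  for (i in c(1, 7, 13, 25)) {
    for (which_p in c("encoder", "decoder")) {
      p1 <- w[[which_p]]; p1[i] <- p1[i] + eps
      p2 <- w[[which_p]]; p2[i] <- p2[i] - eps
      l1 <- if (which_p == "encoder")
        biozbp:::ae_batch_grad(A, p1, w$decoder, cfg$F, o)$loss
      else biozbp:::ae_batch_grad(A, w$encoder, p1, cfg$F, o)$loss
      l2 <- if (which_p == "encoder")
        biozbp:::ae_batch_grad(A, p2, w$decoder, cfg$F, o)$loss
      else biozbp:::ae_batch_grad(A, w$encoder, p2, cfg$F, o)$loss
      ana <- if (which_p == "encoder") g$gW[i] else g$gD[i]
      expect_equal((l1 - l2) / (2 * eps), ana, tolerance = 1e-5)
    }
  }
})

test_that("training fits an exactly representable single-filter system", {
  # K = 1, N = 1: white noise through a known FIR of width <= F
  set.seed(11)
  fir <- c(0.2, 0.5, 0.3)
  x <- rnorm(4000)
  y <- stats::filter(x, fir, sides = 2)
  y[is.na(y)] <- 0
  L <- 32
  n_seg <- floor(length(y) / L)
  segs <- array(0, c(1, L, n_seg))
  for (s in seq_len(n_seg)) segs[1, , s] <- y[((s - 1) * L + 1):(s * L)]
  batch <- structure(list(segments = segs, hop = L, N = 1, K = 1, L = L,
                          n_total = n_seg), class = "segment_batch")
  cfg <- ae_config(N = 1, K = 1, F = 5, L = L, epochs = 150, patience = 150,
                   lr = 1e-2, seed = 3)
  w <- train_autoencoder(batch, cfg)
  h <- attr(w, "loss_history")
  expect_lt(utils::tail(h, 1), 0.10 * h[1])
  expect_identical(w$biases, 0)
  # seeded reproducibility
  w2 <- train_autoencoder(batch, cfg)
  expect_identical(w$encoder, w2$encoder)
  # smoothed trend (10-epoch block means) is non-increasing within jitter
  blocks <- split(h, ceiling(seq_along(h) / 10))
  sm <- vapply(blocks, mean, numeric(1))
  expect_true(all(diff(sm) <= 0.02 * h[1]))
})

test_that("reconstruction matches the hidden source on the study condition", {
  rec <- fix_record()
  tensor <- fix_tensor()
  w <- train_autoencoder(build_segments(tensor, N = 8),
                         ae_config(N = 8, K = 6, F = 9, L = 64, seed = 11))
  recon <- reconstruct_arterial_pulse(w, tensor)
  # bookkeeping: output covers exactly the analyzed samples
  expect_length(recon$series,
                tensor$spans[nrow(tensor$spans), 2] - tensor$spans[1, 1])
  cors <- recon_source_cors(recon, rec)
  expect_gte(stats::median(cors), 0.95)
})

test_that("trained decoder kernels mirror the generator transfer functions", {
  rec <- fix_record()
  tensor <- fix_tensor()
  w <- train_autoencoder(build_segments(tensor, N = 8),
                         ae_config(N = 8, K = 6, F = 9, L = 64, epochs = 150,
                                   patience = 30, tol = 1e-4, seed = 11))
  tr <- make_sensor_transfer("POS1", seed = 2)
  med_len <- round(stats::median(tensor$spans[, 2] - tensor$spans[, 1]))
  f_up <- round(9 * med_len / 64)
  # compare filter responses to a pulse-band probe, best lag, sign-free
  # (the decoder kernel lives on a truncated tap grid, so responses within
  # the signal band are the meaningful object of comparison)
  set.seed(99)
  probe <- biozbp:::lowpass_smooth(rnorm(2000), 250, 15)
  cors <- c()
  for (n_i in 1:8) for (k in 1:6) {
    taps <- stats::approx(seq(0, 1, length.out = 9),
                          w$decoder[(n_i - 1) * 6 + k, ],
                          xout = seq(0, 1, length.out = f_up))$y
    r1 <- biozbp:::conv_same(probe, taps, floor(f_up / 2))
    r2 <- biozbp:::conv_same(probe, tr$coefficients[[k]],
                             floor(length(tr$coefficients[[k]]) / 2))
    cc <- stats::ccf(r1, r2, lag.max = 60, plot = FALSE)$acf
    cors <- c(cors, max(abs(cc)))
  }
  expect_gte(stats::median(cors), 0.8)
})
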