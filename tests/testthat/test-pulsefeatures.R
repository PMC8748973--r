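# Characteristic-point detection and the 15-feature extraction.

test_that("a falling cosine half-period has the closed-form fiducials", {
  fs <- 250
  t <- seq(-0.1, pi + 0.1, length.out = 200)
  beat <- cos(pmin(pmax(t, 0), pi))  # flat shoulders, falling cosine core
  p <- detect_characteristic_points(beat, fs)
  expect_true(p$valid)
  # time axis: index = t * fs + 1
  i0 <- which.min(abs(t - 0)); i1 <- which.min(abs(t - pi))
  im <- which.min(abs(t - pi / 2))
  expect_lt(abs(p$t_dia * fs + 1 - i0), 3)
  expect_lt(abs(p$t_sys * fs + 1 - i1), 3)
  expect_lt(abs(p$t_ms * fs + 1 - im), 3)
})

test_that("all six points match generator truth within two samples", {
  rec <- fix_clean_record()
  src <- rec$truth$source
  fid <- rec$truth$fiducials
  ms <- fid[, "ms"]
  spans <- cbind(ms[-length(ms)], ms[-1])
  pts <- detect_points_record(src, rec$fs, spans, origin = 1)
  ok <- which(pts$valid & !pts$dicrotic_absent)
  expect_gt(length(ok), 0.9 * nrow(pts))
  for (cc in list(c("t_dia", "dia"), c("t_ms", "ms"), c("t_sys", "sys"),
                  c("t_dp", "dp"), c("t_ip", "ip"), c("t_dn", "dn"))) {
    det <- pts$win_start[ok] + pts[[cc[1]]][ok] * rec$fs
    expect_lte(max(abs(det - fid[ok, cc[2]])), 2)
  }
  # ordering invariant on every accepted beat
  with(pts[ok, ], {
    expect_true(all(t_dia <= t_ms & t_ms <= t_sys & t_sys <= t_dp &
                      t_dp <= t_ip & t_ip <= t_dn))
  })
})

test_that("absent dicrotic structure is flagged, never fabricated", {
  model <- arterial_source_model(dicrotic_ratio = 0)
  b <- make_beat_waveform(model, 0.9, 120, 80)
  # window shifted so the main edge is interior (wrap the periodic beat)
  n <- length(b$waveform)
  beat <- c(b$waveform[(n - 20):n], b$waveform[1:(n - 21)])
  p <- detect_characteristic_points(beat, 250)
  expect_true(p$valid)
  expect_true(p$dicrotic_absent)
  expect_true(all(is.na(c(p$t_dp, p$t_ip, p$t_dn))))
  expect_false(anyNA(c(p$t_dia, p$t_ms, p$t_sys)))
  # features degrade gracefully
  expect_true(all(is.na(extract_dicrotic_features(p))))
  expect_true(is.na(extract_time_features(p)[["t_dia_ip"]]))
})

test_that("normalized features are invariant to beat amplitude scaling", {
  rec <- fix_clean_record()
  src <- rec$truth$source
  ms <- rec$truth$fiducials[, "ms"]
  spans <- cbind(ms[-length(ms)], ms[-1])[10:14, ]
  f1 <- extract_beat_features(src, rec$fs, spans, origin = 1)
  f2 <- extract_beat_features(src * 7.3, rec$fs, spans, origin = 1)
  cols <- setdiff(names(f1), c("beat", "valid", "dicrotic_absent"))
  for (cn in cols) expect_equal(f1[[cn]], f2[[cn]], tolerance = 1e-9)
})

test_that("time features scale inversely with the inter-beat interval", {
  p <- data.frame(t_dia = 0.1, t_ms = 0.2, t_sys = 0.3, t_ip = 0.5,
                  t_ibi = 1.0)
  tf1 <- extract_time_features(p)
  p$t_ibi <- 2.0
  expect_equal(extract_time_features(p), tf1 / 2)
  expect_true(all(tf1 >= 0 & tf1 <= 1))
})

test_that("area features hit their closed-form anchors and stay ordered", {
  fs <- 250
  set.seed(8)
  beat <- cumsum(rnorm(100))  # arbitrary window
  # X at the beat end integrates to the full area; X at DIA to none
  pts <- data.frame(t_dia = 0, t_ms = (100 - 1) / fs, t_sys = 0, t_ip = NA,
                    t_ibi = 100 / fs)
  a <- extract_area_features(beat, pts, fs)
  expect_equal(a[["ar_dia_ms"]], 1)
  expect_equal(a[["ar_dia_sys"]], 0)
  expect_true(is.na(a[["ar_dia_ip"]]))
  # detected beats: areas in [0, 1], monotone over MS <= SYS <= IP
  rec <- fix_clean_record()
  ms <- rec$truth$fiducials[, "ms"]
  spans <- cbind(ms[-length(ms)], ms[-1])
  feats <- extract_beat_features(rec$truth$source, rec$fs, spans, origin = 1)
  ok <- feats$valid & !feats$dicrotic_absent
  ar <- feats[ok, c("ar_dia_ms", "ar_dia_sys", "ar_dia_ip")]
  expect_true(all(ar >= 0 & ar <= 1))
  expect_true(all(ar$ar_dia_ms <= ar$ar_dia_sys & ar$ar_dia_sys <= ar$ar_dia_ip))
})

test_that("areas and histograms agree with brute-force oracles", {
  rec <- fix_clean_record()
  fs <- rec$fs
  ms <- rec$truth$fiducials[, "ms"]
  spans <- cbind(ms[-length(ms)], ms[-1])[5:9, ]
  pts <- detect_points_record(rec$truth$source, fs, spans, origin = 1)
  for (b in which(pts$valid)) {
    t_n <- spans[b, 2] - spans[b, 1]
    w0 <- pts$win_start[b]
    beat <- rec$truth$source[w0:(w0 + t_n - 1)]
    a <- extract_area_features(beat, pts[b, ], fs)
    # naive summation oracle
    base <- beat - min(beat)
    i_dia <- round(pts$t_dia[b] * fs) + 1
    naive <- function(i_to) {
      if (i_to == i_dia) return(0)
      s <- 0
      for (i in i_dia:(i_to - 1)) s <- s + (base[i] + base[i + 1]) / 2
      s
    }
    full <- naive(length(beat))
    expect_equal(a[["ar_dia_ms"]], naive(round(pts$t_ms[b] * fs) + 1) / full,
                 tolerance = 1e-9)
    expect_equal(a[["ar_dia_sys"]], naive(round(pts$t_sys[b] * fs) + 1) / full,
                 tolerance = 1e-9)
    # histogram: explicit counting oracle
    h <- extract_histogram_features(beat)
    y <- (beat - min(beat)) / diff(range(beat))
    counts <- integer(5)
    for (v in y) {
      bin <- min(5L, floor(v / 0.2) + 1L)
      counts[bin] <- counts[bin] + 1L
    }
    expect_equal(unname(h), counts / length(y), tolerance = 1e-9)
    expect_equal(sum(h), 1, tolerance = 1e-12)
  }
})

test_that("histogram features handle the canonical shapes", {
  ramp <- seq(0, 1, length.out = 1000)
  expect_equal(unname(extract_histogram_features(ramp)),
               rep(0.2, 5), tolerance = 1e-2)
  expect_error(extract_histogram_features(rep(1, 50)), "flat")
})

test_that("dicrotic amplitude feature grows with the generator ratio", {
  d_amp <- vapply(c(0.3, 0.45, 0.6), function(r) {
    model <- arterial_source_model(dicrotic_ratio = r)
    b <- make_beat_waveform(model, 0.9, 120, 80)
    n <- length(b$waveform)
    beat <- c(b$waveform[(n - 20):n], b$waveform[1:(n - 21)])
    p <- detect_characteristic_points(beat, 250)
    extract_dicrotic_features(p)[["d_amp"]]
  }, numeric(1))
  expect_false(anyNA(d_amp))
  expect_true(all(diff(d_amp) > 0))
  expect_true(all(d_amp >= 0))
})

test_that("median imputation fills only missing feature values", {
  df <- data.frame(beat = 1:4, valid = TRUE, dicrotic_absent = c(F, F, T, F),
                   d_amp = c(0.2, 0.4, NA, 0.6), h1 = c(0.1, 0.2, 0.3, 0.4))
  out <- impute_features(df)
  expect_equal(out$d_amp, c(0.2, 0.4, 0.4, 0.6))
  expect_equal(out$h1, df$h1)
})
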