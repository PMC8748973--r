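# Synthetic multi-channel bio-impedance generator.
#
# Sensing model: a hidden arterial source pulse Y (one quasi-periodic beat
# train), K skin sensors each measuring DC tissue impedance minus the source
# convolved with a location-dependent FIR transfer function, plus white noise.
# Because the source, the filters, the beat boundaries and the per-beat BP are
# all known, every downstream stage can be scored against ground truth.

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generator determinism does not
#' perturb the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Arterial source pulse model
#'
#' Parametric family for one heartbeat of the hidden arterial pulse, in the
#' Bio-Z measurement convention (impedance *falls* on pulse arrival). A beat
#' is the negative of a volume pulse built from three components on the beat
#' phase axis:
#' * a main systolic bump with Gaussian rise (width `systolic_width`) and a
#'   fast Gaussian-to-exponential decay (`decay_width`), peaking at phase
#'   `systolic_peak_frac` (the systolic foot of the Bio-Z beat);
#' * a broad "runoff" component with the same rise and a slow decay
#'   (`runoff_width`, amplitude `runoff_ratio`) carrying the diastolic
#'   relaxation back towards the next diastolic peak;
#' * a Gaussian dicrotic (reflected) wave of relative amplitude
#'   `dicrotic_ratio`, centred `dicrotic_delay` beat periods after the
#'   systolic peak, producing the dicrotic peak/notch pair.
#'
#' `bp_coupling` maps per-beat (SBP, DBP) to multiplicative adjustments of
#' the shape parameters; the default coupling is monotone (see
#' [default_bp_coupling()]) so that BP is recoverable in principle from pulse
#' morphology alone.
#'
#' @param fs Sampling rate in Hz (default 250).
#' @param systolic_peak_frac Phase of the systolic foot within the beat.
#' @param systolic_width Gaussian rise width of the main edge, seconds.
#' @param decay_width Decay scale of the main bump, seconds (exponential tail
#'   time constant is twice this).
#' @param runoff_ratio,runoff_width Amplitude (relative to the main bump) and
#'   decay scale (seconds) of the diastolic runoff component.
#' @param dicrotic_delay Delay of the dicrotic wave after the systolic peak,
#'   as a fraction of the beat period.
#' @param dicrotic_width Width of the dicrotic Gaussian, seconds.
#' @param dicrotic_ratio Dicrotic amplitude relative to the main bump, in
#'   `[0, 1)`; `0` removes the dicrotic structure entirely.
#' @param bp_coupling Function `(model, sbp, dbp) -> list` of effective shape
#'   parameters; defaults to [default_bp_coupling()].
#' @return An object of class `arterial_source_model`.
#' @export
arterial_source_model <- function(fs = 250,
                                  systolic_peak_frac = 0.25,
                                  systolic_width = 0.080,
                                  decay_width = 0.046,
                                  runoff_ratio = 0.35,
                                  runoff_width = 0.23,
                                  dicrotic_delay = 0.30,
                                  dicrotic_width = 0.060,
                                  dicrotic_ratio = 0.45,
                                  bp_coupling = default_bp_coupling) {
  stopifnot(fs > 0, systolic_width > 0, dicrotic_width > 0,
            dicrotic_ratio >= 0, dicrotic_ratio < 1,
            is.function(bp_coupling))
  structure(list(fs = fs,
                 systolic_peak_frac = systolic_peak_frac,
                 systolic_width = systolic_width,
                 decay_width = decay_width,
                 runoff_ratio = runoff_ratio,
                 runoff_width = runoff_width,
                 dicrotic_delay = dicrotic_delay,
                 dicrotic_width = dicrotic_width,
                 dicrotic_ratio = dicrotic_ratio,
                 bp_coupling = bp_coupling),
            class = "arterial_source_model")
}

#' Default monotone BP-to-morphology coupling
#'
#' Normalized excursions `u_s = (SBP - 120)/60`, `u_d = (DBP - 80)/40` and
#' `u_p = (PP - 40)/40` (pulse pressure `PP = SBP - DBP`), each clamped to
#' `[-1, 1]`, modulate the shape parameters multiplicatively:
#' * systolic rise width `x (1 - 0.25 u_s)` — higher SBP, steeper upstroke;
#' * dicrotic amplitude `x (1 + 0.40 u_p)` — higher pulse pressure, larger
#'   reflected wave;
#' * dicrotic delay `x (1 - 0.08 u_d)` — higher DBP, earlier reflection;
#' * runoff amplitude `x (1 + 0.20 u_d)` — higher DBP, fuller diastole.
#'
#' All four maps are strictly monotone in their driving pressure over the
#' physiological range, so the feature-to-BP regression task is well posed on
#' synthetic data.
#'
#' @param model An `arterial_source_model`.
#' @param sbp,dbp Pressures in mmHg.
#' @return Named list of effective shape parameters (widths in seconds,
#'   delay as beat fraction, ratios dimensionless).
#' @export
default_bp_coupling <- function(model, sbp, dbp) {
  u_s <- clamp((sbp - 120) / 60, -1, 1)
  u_d <- clamp((dbp - 80) / 40, -1, 1)
  u_p <- clamp((sbp - dbp - 40) / 40, -1, 1)
  list(systolic_width = model$systolic_width * (1 - 0.25 * u_s),
       decay_width = model$decay_width,
       runoff_ratio = model$runoff_ratio * (1 + 0.20 * u_d),
       runoff_width = model$runoff_width,
       dicrotic_delay = model$dicrotic_delay * (1 - 0.08 * u_d),
       dicrotic_width = model$dicrotic_width,
       dicrotic_ratio = if (model$dicrotic_ratio == 0) 0 else
         clamp(model$dicrotic_ratio * (1 + 0.40 * u_p), 0.02, 0.95))
}

# Gaussian rise / gaussian-to-exponential decay bump on the phase axis.
gex_bump <- function(phi, mu, wl, wr) {
  d <- phi - mu
  out <- numeric(length(phi))
  l <- d < 0
  out[l] <- exp(-0.5 * (d[l] / wl)^2)
  out[!l] <- exp(-d[!l]^2 / (2 * wr * (wr + d[!l])))
  out
}

# Volume pulse (positive bump) for one beat at phase phi, given effective
# parameters in phase units.
volume_pulse <- function(phi, p) {
  v <- gex_bump(phi, p$mu1, p$wl, p$wr) +
    p$a3 * gex_bump(phi, p$mu1, p$wl, p$wr3)
  if (p$r > 0) {
    v <- v + p$r * exp(-0.5 * ((phi - (p$mu1 + p$delay)) / p$w2)^2)
  }
  v
}

# Effective phase-domain parameters for one beat.
beat_phase_params <- function(model, period, sbp, dbp) {
  eff <- model$bp_coupling(model, sbp, dbp)
  list(mu1 = model$systolic_peak_frac,
       wl = eff$systolic_width / period,
       wr = eff$decay_width / period,
       a3 = eff$runoff_ratio,
       wr3 = eff$runoff_width / period,
       delay = eff$dicrotic_delay,
       w2 = eff$dicrotic_width / period,
       r = eff$dicrotic_ratio)
}

#' Generate a single source beat with ground-truth fiducials
#'
#' Evaluates one beat of the arterial source pulse (with periodic extension
#' by one neighbouring beat on each side, so boundary morphology matches a
#' continuous beat train) and locates the six characteristic points on a
#' 4x-oversampled grid by direct extremum search — an oracle path independent
#' of the derivative-zero-crossing detector in the feature module.
#'
#' The diastolic peak of a beat forms where the previous beat's runoff meets
#' the next upstroke, i.e. at the beat boundary; in the periodic single-beat
#' window it therefore appears within about a tenth of a period of either
#' end of the returned waveform (circular convention, see
#' `fiducials["dia"]`).
#'
#' @param model An [arterial_source_model()].
#' @param period Beat period in seconds, within `[0.4, 2]`.
#' @param sbp,dbp Pressures in mmHg (`sbp > dbp`).
#' @return List with `waveform` (length `round(period * fs)`, Bio-Z
#'   convention, unit peak-to-peak), `fiducials` (named sample indices
#'   `dia, ms, sys, dp, ip, dn`; `NA` where the dicrotic structure is
#'   absent), `dicrotic_absent` flag, `period`, `fs`.
#' @export
make_beat_waveform <- function(model, period, sbp, dbp) {
  stopifnot(inherits(model, "arterial_source_model"))
  if (period < 0.4 || period > 2.0) {
    stop("period must lie in [0.4, 2] s", call. = FALSE)
  }
  if (!(sbp > dbp) || sbp > 220 || dbp < 40) {
    stop("require 40 <= dbp < sbp <= 220 mmHg", call. = FALSE)
  }
  fs <- model$fs
  n <- round(period * fs)
  p <- beat_phase_params(model, period, sbp, dbp)
  eval_train <- function(phi) {
    -(volume_pulse(phi, p) + volume_pulse(phi + 1, p) +
        volume_pulse(phi + 2, p) + volume_pulse(phi - 1, p))
  }
  phi <- (seq_len(n) - 1) / n
  x <- eval_train(phi)
  x <- x / (max(x) - min(x))
  # oversampled truth fiducials
  ov <- 4L
  phio <- (seq_len(n * ov) - 1) / (n * ov)
  xo <- eval_train(phio)
  fid_o <- beat_fiducials_idx(xo, circular = TRUE)
  fid <- vapply(fid_o, function(i) {
    if (is.na(i)) NA_real_ else clamp(round((i - 1) / ov) + 1, 1, n)
  }, numeric(1))
  list(waveform = x, fiducials = fid,
       dicrotic_absent = is.na(fid[["dp"]]),
       period = period, fs = fs)
}

# Locate fiducials on one noiseless beat vector by direct extremum search.
# Beat is assumed to start at its onset (systolic peak of the volume pulse at
# ~25% phase). With circular = TRUE the diastolic peak is searched across the
# wrap-around (single-beat case); otherwise in a window just before the onset
# is not available and dia is searched from the window start.
beat_fiducials_idx <- function(x, circular = FALSE) {
  n <- length(x)
  d1 <- c(x[2] - x[1], diff(x))
  pre <- seq_len(max(3L, floor(0.45 * n)))
  sys_i <- pre[which.min(x[pre])]
  if (circular) {
    win <- c(seq(floor(0.85 * n), n), seq_len(max(1L, floor(0.10 * n))))
    dia_i <- win[which.max(x[win])]
  } else {
    dia_i <- which.max(x[seq_len(sys_i)])
  }
  ms_rng <- if (circular) seq_len(sys_i) else dia_i:sys_i
  ms_i <- ms_rng[which.min(d1[ms_rng])]
  out <- list(dia = dia_i, ms = ms_i, sys = sys_i,
              dp = NA_integer_, ip = NA_integer_, dn = NA_integer_)
  aft <- which(seq_len(n) > sys_i & seq_len(n) < floor(0.9 * n))
  if (length(aft) > 3) {
    xs <- x[c(aft, max(aft) + 1L)]
    lm <- aft[which(diff(sign(diff(xs))) < 0)]
    if (length(lm)) {
      dp_i <- lm[1] + 1L
      aft2 <- which(seq_len(n) > dp_i & seq_len(n) < floor(0.9 * n))
      if (length(aft2) > 2) {
        xs2 <- x[c(aft2, max(aft2) + 1L)]
        lmin <- aft2[which(diff(sign(diff(xs2))) > 0)]
        if (length(lmin)) {
          dn_i <- lmin[1] + 1L
          ipc <- dp_i:dn_i
          ip_i <- ipc[which.min(d1[ipc])]
          out$dp <- dp_i; out$ip <- ip_i; out$dn <- dn_i
        }
      }
    }
  }
  out
}

#' Generate a blood-pressure trial trajectory
#'
#' Emulates repeated BP maneuver trials: a gradual handgrip rise of about
#' `rise` mmHg above baseline, a cold-pressor hold that keeps BP elevated,
#' and an exponential recovery back to baseline, with seeded AR(1) beat-wise
#' jitter. DBP follows the SBP profile at 45% amplitude with its own jitter.
#'
#' @param n_trials Number of trials (default 12, of which a study would use
#'   the first 6 at the primary location).
#' @param beats_per_phase Integer vector `c(handgrip, cold, rest)` of beats
#'   per trial phase; the default corresponds to 3 / 1 / 3.5 minutes at about
#'   65 beats/min.
#' @param sbp_base,dbp_base Baseline pressures, mmHg.
#' @param rise Peak SBP elevation above baseline, mmHg (default 50).
#' @param jitter_sd Innovation SD of the AR(1) beat-wise jitter, mmHg.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return Object of class `bp_trajectory`: per-beat `sbp`, `dbp` (mmHg),
#'   `trial_id`, and `trial_boundaries` (first beat index of each trial).
#' @export
make_bp_trajectory <- function(n_trials = 12,
                               beats_per_phase = c(handgrip = 195, cold = 65, rest = 227),
                               sbp_base = 120, dbp_base = 78,
                               rise = 50, jitter_sd = 1.0, seed = 1) {
  stopifnot(n_trials >= 1, length(beats_per_phase) == 3, all(beats_per_phase >= 1))
  n_h <- beats_per_phase[[1]]; n_c <- beats_per_phase[[2]]; n_r <- beats_per_phase[[3]]
  per_trial <- n_h + n_c + n_r
  profile <- c(rise * (1 - cos(pi * seq_len(n_h) / n_h)) / 2,          # ramp up
               rise * seq(1, 0.70, length.out = n_c),                  # cold hold
               rise * 0.70 * exp(-3 * seq_len(n_r) / n_r))             # recovery
  n <- per_trial * n_trials
  with_seed(seed, {
    sbp_j <- as.numeric(stats::filter(stats::rnorm(n, 0, jitter_sd), 0.9,
                                      method = "recursive"))
    dbp_j <- as.numeric(stats::filter(stats::rnorm(n, 0, 0.7 * jitter_sd), 0.9,
                                      method = "recursive"))
  })
  sbp <- sbp_base + rep(profile, n_trials) + sbp_j
  dbp <- dbp_base + 0.45 * rep(profile, n_trials) + dbp_j
  sbp <- clamp(sbp, 70, 220)
  dbp <- clamp(dbp, 40, sbp - 15)
  structure(list(sbp = sbp, dbp = dbp,
                 trial_id = rep(seq_len(n_trials), each = per_trial),
                 trial_boundaries = seq(1L, n, by = per_trial)),
            class = "bp_trajectory")
}

#' Sensor-array transfer functions for a sensing location
#'
#' Builds K FIR filters relating the hidden arterial source to each Bio-Z
#' channel. Channels are arranged two per electrode column over three
#' columns; each channel's distance to the artery is the column offset from
#' the artery position plus a seeded per-row offset. Attenuation (gain
#' `1/(1 + 0.6 d)`), smoothing (Gaussian tap width `0.6 + 15 d` samples),
#' group delay (`4 d` samples) and a negative trailing lobe (relative
#' amplitude `0.35 min(d, 1.2)`, lagging by two tap widths) all grow with
#' distance `d`, so distant channels are smaller, smoother and visibly
#' reshaped — the morphology change that makes the sensing location matter.
#'
#' Locations: `POS1` has the artery at the middle column; `POS2`/`POS3`
#' shift the artery one column right/left, so their distance maps equal
#' POS1's shifted by one column (same seed); `ReAttach` draws a random
#' artery offset in `[-1, 1]` columns.
#'
#' @param location_id One of `"POS1"`, `"POS2"`, `"POS3"`, `"ReAttach"`.
#' @param K Number of channels (default 6; two per column).
#' @param seed RNG seed controlling row offsets and the ReAttach artery
#'   position.
#' @param n_taps FIR length (odd, default 21).
#' @param fs Sampling rate the taps are designed at (must match the source
#'   model when synthesizing).
#' @param family `"gaussian"` (location-dependent low-pass) or `"delta"`
#'   (identity filters on every channel, for oracle tests).
#' @return Object of class `sensor_transfer` with per-channel `coefficients`,
#'   `gain`, `distance`, plus `location_id`, `fs`, `K`.
#' @export
make_sensor_transfer <- function(location_id = c("POS1", "POS2", "POS3", "ReAttach"),
                                 K = 6, seed = 1, n_taps = 81, fs = 250,
                                 family = c("gaussian", "delta")) {
  location_id <- match.arg(location_id)
  family <- match.arg(family)
  stopifnot(K >= 1, n_taps %% 2 == 1)
  cols <- ceiling(seq_len(K) / 2)
  rows <- (seq_len(K) - 1) %% 2 + 1
  art <- with_seed(seed, {
    row_off <- stats::runif(2, 0, 0.3)
    a <- switch(location_id,
                POS1 = 2, POS2 = 1, POS3 = 3,
                ReAttach = 2 + stats::runif(1, -1, 1))
    list(a = a, row_off = row_off)
  })
  d <- abs(cols - art$a) + art$row_off[rows]
  gain <- 1 / (1 + 0.6 * d)
  mid <- (n_taps + 1) / 2
  coefficients <- lapply(seq_len(K), function(k) {
    if (family == "delta") {
      taps <- numeric(n_taps); taps[mid] <- 1
      return(taps)
    }
    sdk <- 0.6 + 15 * d[k]
    grid <- seq_len(n_taps)
    taps <- stats::dnorm(grid, mean = mid + 4 * d[k], sd = sdk) -
      0.35 * min(d[k], 1.2) *
        stats::dnorm(grid, mean = mid + 4 * d[k] + 2 * sdk, sd = 1.5 * sdk)
    taps / sum(taps) * gain[k]
  })
  if (family == "delta") gain <- rep(1, K)
  structure(list(location_id = location_id, K = K, fs = fs,
                 coefficients = coefficients, gain = gain,
                 distance = d, n_taps = n_taps, family = family, seed = seed),
            class = "sensor_transfer")
}

#' Synthesize a multi-channel Bio-Z recording
#'
#' Builds the hidden source beat train from the source model and per-beat BP,
#' filters it through each channel's transfer function, and adds a slowly
#' varying DC component (spline through seeded random-walk knots, bounded,
#' band-limited well below 0.05 Hz by construction) and white measurement
#' noise. Channel samples follow
#' `DC - pulse_scale * (volume pulse %conv% coefficients) + noise`, so the
#' impedance falls on pulse arrival; the stored ground-truth `source` uses
#' the same (falling) convention.
#'
#' @param model An [arterial_source_model()].
#' @param transfer A [make_sensor_transfer()] result with matching `fs`.
#' @param trajectory A [make_bp_trajectory()] result (one beat per entry).
#' @param dc_params List: `mean` (Ohm, default 50), `drift_amp` (random-walk
#'   step SD, Ohm), `drift_max` (bound on drift excursion, Ohm), `knot_s`
#'   (knot spacing, s).
#' @param noise_params List with either `snr_db` (per-channel white noise at
#'   this SNR relative to the channel's pulsatile RMS) or `sd` (Ohm; `0`
#'   for noiseless).
#' @param hr_bpm Mean heart rate (default 65).
#' @param hr_jitter_sd Relative AR(1) jitter of beat periods.
#' @param pulse_scale Source-to-impedance scale in Ohm (default 0.115, giving
#'   channel pulsatile peak-to-peak amplitudes in the 50-150 mOhm range).
#' @param seed RNG seed.
#' @return Object of class `bioz_record`: `samples` (K x T, Ohm), `fs`,
#'   `location_id`, `bp` (the trajectory), and `truth` (hidden source,
#'   beat onsets/periods in samples, per-beat fiducial indices, per-channel
#'   noiseless pulsatile component and DC).
#' @export
synthesize_recording <- function(model, transfer, trajectory,
                                 dc_params = list(), noise_params = list(),
                                 hr_bpm = 65, hr_jitter_sd = 0.015,
                                 pulse_scale = 0.115, seed = 1) {
  stopifnot(inherits(model, "arterial_source_model"),
            inherits(transfer, "sensor_transfer"),
            inherits(trajectory, "bp_trajectory"))
  if (!isTRUE(all.equal(model$fs, transfer$fs))) {
    stop("model and transfer sampling rates differ", call. = FALSE)
  }
  dc <- utils::modifyList(list(mean = 50, drift_amp = 0.03, drift_max = 0.4,
                               knot_s = 20), dc_params)
  noise <- utils::modifyList(list(snr_db = 20, sd = NULL), noise_params)
  fs <- model$fs
  K <- transfer$K
  n_beats <- length(trajectory$sbp)

  res <- with_seed(seed, {
    pj <- as.numeric(stats::filter(stats::rnorm(n_beats, 0, hr_jitter_sd), 0.8,
                                   method = "recursive"))
    periods <- clamp((60 / hr_bpm) * (1 + pj), 0.4, 2.0)
    onsets_s <- cumsum(c(0, periods[-n_beats]))
    total_s <- sum(periods)
    n_total <- ceiling(total_s * fs)
    tgrid <- (seq_len(n_total) - 1) / fs

    # hidden volume-pulse train: each beat contributes over [-0.5, 1.5] periods
    v <- numeric(n_total)
    beat_params <- vector("list", n_beats)
    for (b in seq_len(n_beats)) {
      p <- beat_phase_params(model, periods[b], trajectory$sbp[b], trajectory$dbp[b])
      beat_params[[b]] <- p
      # each beat contributes over [-0.5, 3] periods; the slow runoff tail is
      # cosine-tapered to zero over the last half period so truncation leaves
      # no step in the summed signal
      lo <- max(1L, floor((onsets_s[b] - 0.5 * periods[b]) * fs) + 1L)
      hi <- min(n_total, ceiling((onsets_s[b] + 3.0 * periods[b]) * fs) + 1L)
      idx <- lo:hi
      phi <- (tgrid[idx] - onsets_s[b]) / periods[b]
      taper <- ifelse(phi <= 2.5, 1,
                      0.5 * (1 + cos(pi * clamp((phi - 2.5) / 0.5, 0, 1))))
      v[idx] <- v[idx] + taper * volume_pulse(phi, p)
    }
    onset_idx <- pmin(round(onsets_s * fs) + 1L, n_total)
    period_n <- round(periods * fs)
    # normalize the source to median per-beat peak-to-peak of 1
    p2p <- vapply(seq_len(n_beats), function(b) {
      idx <- onset_idx[b]:min(n_total, onset_idx[b] + period_n[b] - 1L)
      diff(range(v[idx]))
    }, numeric(1))
    v <- v / stats::median(p2p)
    source <- -v

    # per-channel pulsatile + DC + noise
    samples <- matrix(0, nrow = K, ncol = n_total)
    pulsatile <- matrix(0, nrow = K, ncol = n_total)
    dc_mat <- matrix(0, nrow = K, ncol = n_total)
    n_knots <- max(4L, ceiling(total_s / dc$knot_s) + 1L)
    knot_t <- seq(0, total_s, length.out = n_knots)
    for (k in seq_len(K)) {
      pul <- -pulse_scale * conv_same(v, transfer$coefficients[[k]])
      walk <- cumsum(stats::rnorm(n_knots, 0, dc$drift_amp))
      walk <- clamp(walk - walk[1], -dc$drift_max, dc$drift_max)
      dck <- dc$mean + stats::spline(knot_t, walk, xout = tgrid)$y
      sdk <- if (!is.null(noise$sd)) noise$sd else
        sqrt(mean(pul^2)) * 10^(-noise$snr_db / 20)
      samples[k, ] <- dck + pul +
        if (sdk > 0) stats::rnorm(n_total, 0, sdk) else 0
      pulsatile[k, ] <- pul
      dc_mat[k, ] <- dck
    }
    fiducials <- truth_fiducials(source, onset_idx, period_n)
    list(samples = samples, pulsatile = pulsatile, dc = dc_mat,
         source = source, onset_idx = onset_idx, period_n = period_n,
         fiducials = fiducials)
  })

  structure(list(samples = res$samples, fs = fs, K = K,
                 location_id = transfer$location_id,
                 bp = trajectory,
                 truth = list(source = res$source,
                              onset_idx = res$onset_idx,
                              period_n = res$period_n,
                              fiducials = res$fiducials,
                              pulsatile = res$pulsatile,
                              dc = res$dc),
                 params = list(pulse_scale = pulse_scale, hr_bpm = hr_bpm,
                               dc = dc, noise = noise, seed = seed)),
            class = "bioz_record")
}

# Ground-truth fiducials for every beat of a noiseless source series, by
# direct extremum search in onset-anchored windows (oracle path, independent
# of the feature module's detector).
truth_fiducials <- function(source, onset_idx, period_n) {
  n_beats <- length(onset_idx)
  n <- length(source)
  out <- matrix(NA_real_, nrow = n_beats, ncol = 6,
                dimnames = list(NULL, c("dia", "ms", "sys", "dp", "ip", "dn")))
  d1 <- deriv1(source)
  for (b in seq_len(n_beats)) {
    a <- onset_idx[b]; Tn <- period_n[b]
    hi <- min(n, a + Tn - 1L)
    # systolic foot: global min in the first 45% of the beat
    pre <- a:min(hi, a + floor(0.45 * Tn))
    sys_i <- pre[which.min(source[pre])]
    # diastolic peak: max in a window straddling the onset
    dwin <- max(1L, a - floor(0.12 * Tn)):min(hi, a + floor(0.12 * Tn))
    dia_i <- dwin[which.max(source[dwin])]
    if (dia_i >= sys_i) next
    ms_rng <- dia_i:sys_i
    ms_i <- ms_rng[which.min(d1[ms_rng])]
    out[b, c("dia", "ms", "sys")] <- c(dia_i, ms_i, sys_i)
    aft <- (sys_i + 1L):min(hi, a + floor(0.9 * Tn))
    if (length(aft) > 4) {
      xs <- source[c(aft, min(n, max(aft) + 1L))]
      lm <- aft[which(diff(sign(diff(xs))) < 0)]
      if (length(lm)) {
        dp_i <- lm[1] + 1L
        aft2 <- (dp_i + 1L):min(hi, a + floor(0.9 * Tn))
        if (length(aft2) > 2) {
          xs2 <- source[c(aft2, min(n, max(aft2) + 1L))]
          lmin <- aft2[which(diff(sign(diff(xs2))) > 0)]
          if (length(lmin)) {
            dn_i <- lmin[1] + 1L
            ipc <- dp_i:dn_i
            out[b, c("dp", "ip", "dn")] <-
              c(dp_i, ipc[which.min(d1[ipc])], dn_i)
          }
        }
      }
    }
  }
  out
}

#' @export
print.bioz_record <- function(x, ...) {
  cat(sprintf("<bioz_record> %d channels x %d samples @ %g Hz, location %s\n",
              x$K, ncol(x$samples), x$fs, x$location_id))
  cat(sprintf("  %d beats, SBP %.1f-%.1f mmHg, DBP %.1f-%.1f mmHg\n",
              length(x$bp$sbp), min(x$bp$sbp), max(x$bp$sbp),
              min(x$bp$dbp), max(x$bp$dbp)))
  invisible(x)
}
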