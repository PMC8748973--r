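# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# ~150-beat POS1 recording at the study noise level (20 dB SNR)
fix_record <- function() fixture("record", function() {
  model <- arterial_source_model()
  traj <- make_bp_trajectory(n_trials = 1, beats_per_phase = c(60, 20, 70),
                             seed = 3)
  transfer <- make_sensor_transfer("POS1", seed = 2)
  synthesize_recording(model, transfer, traj, seed = 5)
})

# noiseless recording with identity (delta) transfer functions
fix_clean_record <- function() fixture("clean_record", function() {
  model <- arterial_source_model()
  traj <- make_bp_trajectory(n_trials = 1, beats_per_phase = c(50, 15, 55),
                             seed = 7)
  transfer <- make_sensor_transfer("POS1", seed = 2, family = "delta")
  synthesize_recording(model, transfer, traj, noise_params = list(sd = 0),
                       seed = 9)
})

fix_pulse_set <- function() fixture("pulse_set", function() {
  preprocess_record(fix_record())
})

fix_clean_pulse_set <- function() fixture("clean_pulse_set", function() {
  preprocess_record(fix_clean_record())
})

fix_tensor <- function() fixture("tensor", function() {
  build_beat_tensor(fix_pulse_set(), L = 64)
})

# per-beat lag-searched NCC between a reconstruction and the hidden source
recon_source_cors <- function(recon, record) {
  spans <- recon$beat_spans
  vapply(seq_len(nrow(spans)), function(b) {
    i <- (spans[b, 1]:(spans[b, 2] - 1)) - spans[1, 1] + 1
    ncc_best_lag(recon$series[i],
                 record$truth$source[spans[b, 1]:(spans[b, 2] - 1)])
  }, numeric(1))
}
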