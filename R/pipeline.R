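# End-to-end orchestration: generate (or load) recordings per sensing
# location, preprocess, segment, train one autoencoder per location
# (AE1-AE4), reconstruct the arterial pulse, extract features, and run the
# evaluation protocols.

#' Pipeline configuration
#'
#' One list gathering every stage's parameters with the package defaults;
#' any field can be overridden via `...`.
#'
#' @param seed Global seed; per-location seeds are derived from it.
#' @param ... Overrides for any default field, e.g. `locations`,
#'   `trials_per_location`, `beats_per_phase`, `snr_db`, `L`, `N`, `F`,
#'   `epochs`, `protocols`, `n_estimators`, `max_depth`,
#'   `average_window`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(seed = seed,
              fs = 250,
              locations = c("POS1", "POS2", "POS3", "ReAttach"),
              trials_per_location = c(POS1 = 6, POS2 = 2, POS3 = 2, ReAttach = 2),
              beats_per_phase = c(handgrip = 195, cold = 65, rest = 227),
              hr_bpm = 65,
              snr_db = 20,
              K = 6,
              L = 64, N = 8, F = 9,
              epochs = 200, lr = 1e-3, batch = 32, max_segments = 1200,
              protocols = c("kfold20", "leave_one_trial", "cross_location"),
              n_estimators = 32, max_depth = 8, min_train = 100,
              average_window = 20, smooth_window = 20,
              n_folds = 20, n_train_trials = 4)
  override <- list(...)
  cfg[names(override)] <- override
  class(cfg) <- "pipeline_config"
  cfg
}

#' Process one recording through reconstruction and feature extraction
#'
#' preprocess -> beat tensor -> segments -> autoencoder training (one model
#' for this recording's location) -> arterial pulse reconstruction ->
#' characteristic points -> features.
#'
#' @param record A `bioz_record`.
#' @param config A [pipeline_config()].
#' @return List: `pulse_set`, `tensor`, `weights`, `recon`, `features`,
#'   `ae_label`.
#' @export
process_recording <- function(record, config = pipeline_config()) {
  ps <- preprocess_record(record)
  tensor <- build_beat_tensor(ps, L = config$L)
  segs <- build_segments(tensor, N = config$N)
  aecfg <- ae_config(N = config$N, K = record$K, F = config$F, L = config$L,
                     lr = config$lr, epochs = config$epochs,
                     batch = config$batch, max_segments = config$max_segments,
                     seed = config$seed)
  w <- train_autoencoder(segs, aecfg)
  recon <- reconstruct_arterial_pulse(w, tensor)
  feats <- extract_beat_features(recon$series, record$fs, recon$beat_spans)
  list(pulse_set = ps, tensor = tensor, weights = w, recon = recon,
       features = feats, ae_label = ae_model_label(record$location_id))
}

#' Run the full synthetic pipeline
#'
#' Generates one recording per configured location (same source model,
#' location-specific transfer functions, independent BP trial profiles),
#' processes each through its own autoencoder, assembles the multi-location
#' BP dataset, and runs the configured evaluation protocols.
#'
#' @param config A [pipeline_config()].
#' @param keep_artifacts Keep per-location intermediate artifacts in the
#'   result (default FALSE to save memory).
#' @return List of class `pipeline_result`: `reports` (one
#'   `protocol_report` per protocol), `dataset`, `registry`
#'   (AE label -> trained weights), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), keep_artifacts = FALSE) {
  model <- arterial_source_model(fs = config$fs)
  registry <- list()
  datasets <- list()
  artifacts <- list()
  for (i in seq_along(config$locations)) {
    loc <- config$locations[i]
    n_trials <- config$trials_per_location[[loc]]
    traj <- make_bp_trajectory(n_trials = n_trials,
                               beats_per_phase = config$beats_per_phase,
                               seed = config$seed + 100 * i)
    transfer <- make_sensor_transfer(loc, K = config$K, seed = config$seed,
                                     fs = config$fs)
    rec <- synthesize_recording(model, transfer, traj,
                                noise_params = list(snr_db = config$snr_db),
                                hr_bpm = config$hr_bpm,
                                seed = config$seed + 1000 * i)
    proc <- process_recording(rec, config)
    registry[[proc$ae_label]] <- proc$weights
    datasets[[loc]] <- make_bp_dataset(proc$features, traj,
                                       location_id = loc,
                                       smooth_window = config$smooth_window)
    if (keep_artifacts) artifacts[[loc]] <- proc
  }
  dataset <- do.call(bind_bp_datasets, unname(datasets))
  reports <- list()
  for (p in config$protocols) {
    reports[[p]] <- run_protocol(dataset, p,
                                 n_folds = config$n_folds,
                                 n_train_trials = config$n_train_trials,
                                 average_window = config$average_window,
                                 seed = config$seed,
                                 n_estimators = config$n_estimators,
                                 max_depth = config$max_depth,
                                 min_train = config$min_train)
  }
  structure(list(reports = reports, dataset = dataset, registry = registry,
                 artifacts = artifacts, config = config),
            class = "pipeline_result")
}
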