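# Record persistence: a directory-based hierarchical container (one group
# per pipeline stage, CSV matrices + a JSON manifest) and a flat single-file
# CSV dialect for small fixtures.

#' Write a recording to a directory container
#'
#' Layout: `manifest.json` (fs, location, sizes), `signals.csv` (one column
#' per channel, Ohm), `bp.csv` (per-beat sbp/dbp/trial), and a `truth/`
#' group (hidden source, beat table with fiducials) when ground truth is
#' present. Derived stages can be added next to these with
#' [write_group_csv()].
#'
#' @param record A `bioz_record`.
#' @param path Container directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "bioz_record"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(format = "biozbp-record", version = 1L,
                   fs = record$fs, K = record$K,
                   location_id = record$location_id,
                   n_samples = ncol(record$samples),
                   n_beats = length(record$bp$sbp),
                   has_truth = !is.null(record$truth))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  sig <- data.table::as.data.table(t(record$samples))
  data.table::setnames(sig, paste0("ch", seq_len(record$K)))
  data.table::fwrite(sig, file.path(path, "signals.csv"))
  if (!is.null(record$bp)) {
    data.table::fwrite(data.table::data.table(sbp = record$bp$sbp,
                                              dbp = record$bp$dbp,
                                              trial_id = record$bp$trial_id),
                       file.path(path, "bp.csv"))
  }
  if (!is.null(record$truth)) {
    dir.create(file.path(path, "truth"), showWarnings = FALSE)
    data.table::fwrite(data.table::data.table(source = record$truth$source),
                       file.path(path, "truth", "source.csv"))
    beats <- data.table::data.table(onset_idx = record$truth$onset_idx,
                                    period_n = record$truth$period_n)
    beats <- cbind(beats, data.table::as.data.table(record$truth$fiducials))
    data.table::fwrite(beats, file.path(path, "truth", "beats.csv"))
  }
  invisible(path)
}

#' Read a recording from a directory container
#' @param path Container directory written by [write_record()].
#' @return A `bioz_record` (without the per-channel noiseless components,
#'   which are not persisted).
#' @export
read_record <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    stop("not a record container (missing manifest.json): ", path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "biozbp-record")) {
    stop("unrecognized container format", call. = FALSE)
  }
  sig <- data.table::fread(file.path(path, "signals.csv"))
  samples <- t(as.matrix(sig))
  dimnames(samples) <- NULL
  bp <- NULL
  if (file.exists(file.path(path, "bp.csv"))) {
    b <- data.table::fread(file.path(path, "bp.csv"))
    bp <- structure(list(sbp = b$sbp, dbp = b$dbp, trial_id = b$trial_id,
                         trial_boundaries = which(c(TRUE, diff(b$trial_id) != 0))),
                    class = "bp_trajectory")
  }
  truth <- NULL
  if (file.exists(file.path(path, "truth", "source.csv"))) {
    src <- data.table::fread(file.path(path, "truth", "source.csv"))
    beats <- data.table::fread(file.path(path, "truth", "beats.csv"))
    truth <- list(source = src$source,
                  onset_idx = beats$onset_idx, period_n = beats$period_n,
                  fiducials = as.matrix(beats[, c("dia", "ms", "sys",
                                                  "dp", "ip", "dn")]))
  }
  structure(list(samples = samples, fs = manifest$fs, K = manifest$K,
                 location_id = manifest$location_id, bp = bp, truth = truth,
                 params = NULL),
            class = "bioz_record")
}

#' Write a derived table into a record container group
#' @param x A data.frame/matrix.
#' @param path Container directory.
#' @param group Group name (file `group.csv` inside the container).
#' @return The file path, invisibly.
#' @export
write_group_csv <- function(x, path, group) {
  f <- file.path(path, paste0(group, ".csv"))
  data.table::fwrite(data.table::as.data.table(x), f)
  invisible(f)
}

#' Write a recording as a flat CSV fixture
#'
#' Single file: a `# fs=<Hz> location_id=<id>` comment line, then a header
#' row and one column per channel. BP and truth are not carried by this
#' dialect.
#'
#' @param record A `bioz_record`.
#' @param file Output file.
#' @return `file`, invisibly.
#' @export
write_record_csv <- function(record, file) {
  stopifnot(inherits(record, "bioz_record"))
  con <- file(file, "w")
  writeLines(sprintf("# fs=%g location_id=%s", record$fs, record$location_id), con)
  close(con)
  sig <- data.table::as.data.table(t(record$samples))
  data.table::setnames(sig, paste0("ch", seq_len(record$K)))
  data.table::fwrite(sig, file, append = TRUE, col.names = TRUE)
  invisible(file)
}

#' Read a flat CSV recording
#' @param file File written by [write_record_csv()].
#' @return A `bioz_record` (no BP, no truth).
#' @export
read_record_csv <- function(file) {
  first <- readLines(file, n = 1)
  m <- regmatches(first, regexec("^# fs=([0-9.]+) location_id=(\\S+)", first))[[1]]
  if (length(m) != 3) {
    stop("format error: missing '# fs=... location_id=...' header line",
         call. = FALSE)
  }
  sig <- data.table::fread(file, skip = 1)
  samples <- t(as.matrix(sig))
  dimnames(samples) <- NULL
  structure(list(samples = samples, fs = as.numeric(m[2]), K = nrow(samples),
                 location_id = m[3], bp = NULL, truth = NULL, params = NULL),
            class = "bioz_record")
}
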