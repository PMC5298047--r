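#' Construct an EMG recording
#'
#' Container for a continuous single-channel electromyogram: a numeric sample
#' vector (in microvolts) plus its sampling rate. All downstream stages
#' (filtering, epoching, model inversion, peak scoring) consume this class.
#'
#' @param samples numeric vector of EMG samples (microvolts); must be finite
#'   and non-empty.
#' @param sampling_rate sampling rate in Hz (positive scalar).
#' @param subject_id opaque subject label.
#' @param channel_label opaque channel label.
#' @return an object of class `emg_recording`: a list with fields `samples`,
#'   `sampling_rate`, `subject_id`, `channel_label` and a `provenance` list
#'   recording processing steps applied so far.
#' @export
emg_recording <- function(samples, sampling_rate, subject_id = "s01",
                          channel_label = "emg") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("emg_recording: need at least one sample")
  if (!all(is.finite(samples)))
    stop("emg_recording: samples must be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("emg_recording: sampling_rate must be a positive number")
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         subject_id = as.character(subject_id),
         channel_label = as.character(channel_label),
         provenance = list()),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> subject=%s channel=%s: %d samples @ %g Hz (%.2f s)\n",
              x$subject_id, x$channel_label, length(x$samples),
              x$sampling_rate, length(x$samples) / x$sampling_rate))
  if (length(x$provenance))
    cat("  processing:", paste(vapply(x$provenance, `[[`, "", "step"),
                               collapse = " -> "), "\n")
  invisible(x)
}

#' @export
length.emg_recording <- function(x) length(x$samples)

#' Recording duration in seconds
#' @param rec an `emg_recording`.
#' @return duration in seconds.
#' @export
duration <- function(rec) length(rec$samples) / rec$sampling_rate

# append a provenance entry; internal
add_provenance <- function(rec, step, ...) {
  rec$provenance <- c(rec$provenance, list(c(list(step = step), list(...))))
  rec
}

#' Map an onset time to a sample index
#'
#' Onsets are seconds from recording start; the onset sample is
#' `floor(onset * rate)` (0-based), i.e. the first sample at or after the
#' event, so an epoch never reads data preceding the event.
#'
#' @param onset onset time(s) in seconds.
#' @param rate sampling rate in Hz.
#' @return 0-based sample index (add 1 for R vector indexing).
#' @export
onset_sample <- function(onset, rate) floor(onset * rate)

#' Read a continuous EMG recording from delimited text
#'
#' Accepts one-column (value) or two-column (time, value) comma- or
#' tab-delimited text with a single header line. The sampling rate is taken
#' from a `# sampling_rate: <Hz>` comment line if present, otherwise from the
#' `sampling_rate` argument.
#'
#' @param path file path.
#' @param sampling_rate sampling rate in Hz; required when the file carries no
#'   `# sampling_rate:` comment.
#' @param subject_id,channel_label labels attached to the recording.
#' @return an [emg_recording()].
#' @export
read_emg <- function(path, sampling_rate = NULL, subject_id = "s01",
                     channel_label = "emg") {
  if (!file.exists(path)) stop("read_emg: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  rate_line <- grep("sampling_rate", meta, value = TRUE)
  if (length(rate_line)) {
    sampling_rate <- as.numeric(sub(".*sampling_rate[:=]?\\s*", "", rate_line[1]))
  }
  if (is.null(sampling_rate) || !is.finite(sampling_rate))
    stop("read_emg: sampling rate missing; declare it in the file header ",
         "('# sampling_rate: <Hz>') or pass sampling_rate=")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("read_emg: parse error: no data rows in ", path)
  sep <- if (grepl("\t", body[1])) "\t" else ","
  dat <- utils::read.table(text = paste(body, collapse = "\n"), sep = sep,
                           header = TRUE, colClasses = "character")
  vcol <- if (ncol(dat) >= 2L) 2L else 1L
  vals <- suppressWarnings(as.numeric(dat[[vcol]]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("read_emg: parse error at data line %d: non-numeric sample %s",
                 bad, shQuote(dat[[vcol]][bad])))
  }
  emg_recording(vals, sampling_rate, subject_id = subject_id,
                channel_label = channel_label)
}

#' Write an EMG recording as delimited text
#'
#' Emits a `# sampling_rate:` comment followed by a single `value` column, the
#' format [read_emg()] reads back.
#'
#' @param rec an `emg_recording`.
#' @param path output path.
#' @param digits significant digits retained.
#' @return `path`, invisibly.
#' @export
write_emg <- function(rec, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate: %s", format(rec$sampling_rate)), con)
  writeLines("value", con)
  writeLines(formatC(rec$samples, digits = digits, format = "g"), con)
  invisible(path)
}

CS_TYPES <- c("CSP", "CSM", "NONE")

#' Validate an event table
#'
#' Checks the invariants of the trial/event bookkeeping: required columns,
#' known CS types, non-negative onsets, per-subject unique trial indices and
#' strictly increasing sound onsets, and (when a recording duration is given)
#' onsets within the recording.
#'
#' @param events data.frame with columns `subject_id`, `trial_index`,
#'   `sound_onset`, `cs_onset`, `cs_type`, `us_delivered`.
#' @param duration optional recording duration (seconds) or named vector of
#'   durations per subject; onsets beyond it are rejected.
#' @param epoch_window optional epoch length (seconds); onsets whose epoch
#'   would overrun the recording are rejected.
#' @return the validated events data.frame (types normalised), invisibly
#'   usable downstream.
#' @export
validate_events <- function(events, duration = NULL, epoch_window = 0) {
  req <- c("subject_id", "trial_index", "sound_onset", "cs_type")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop("validate_events: missing column(s): ", paste(miss, collapse = ", "))
  events$subject_id <- as.character(events$subject_id)
  events$trial_index <- as.integer(events$trial_index)
  events$sound_onset <- as.numeric(events$sound_onset)
  if (!"cs_onset" %in% names(events)) events$cs_onset <- NA_real_
  if (!"us_delivered" %in% names(events)) events$us_delivered <- FALSE
  events$us_delivered <- as.logical(events$us_delivered)
  bad_cs <- !events$cs_type %in% CS_TYPES
  if (any(bad_cs))
    stop("validate_events: unknown cs_type ",
         shQuote(events$cs_type[which(bad_cs)[1]]), " in row ", which(bad_cs)[1],
         " (expected CSP, CSM or NONE)")
  if (any(events$trial_index < 0L))
    stop("validate_events: negative trial_index in row ",
         which(events$trial_index < 0L)[1])
  if (any(events$sound_onset < 0))
    stop("validate_events: negative sound_onset in row ",
         which(events$sound_onset < 0)[1])
  for (sid in unique(events$subject_id)) {
    rows <- which(events$subject_id == sid)
    ti <- events$trial_index[rows]
    if (anyDuplicated(ti))
      stop("validate_events: duplicate trial_index ", ti[duplicated(ti)][1],
           " for subject ", sid)
    ons <- events$sound_onset[rows]
    if (is.unsorted(ons, strictly = TRUE)) {
      off <- rows[which(diff(ons) <= 0)[1] + 1L]
      stop("validate_events: sound onsets not strictly increasing for subject ",
           sid, " at row ", off)
    }
    if (!is.null(duration)) {
      dur <- if (length(duration) > 1L) duration[[sid]] else duration
      over <- ons + epoch_window > dur
      if (any(over))
        stop("validate_events: onset ", ons[over][1], " s (+ epoch) exceeds ",
             "recording duration ", dur, " s for subject ", sid,
             " (trial ", ti[over][1], ")")
    }
  }
  events
}

#' Read an event table from delimited text
#'
#' Comma- or tab-delimited text with one header line and columns
#' `subject_id`, `trial_index`, `sound_onset`, and optionally `cs_onset`,
#' `cs_type`, `us_delivered`. The table is validated on load.
#'
#' @inheritParams validate_events
#' @param path file path.
#' @return validated events data.frame.
#' @export
read_events <- function(path, duration = NULL, epoch_window = 0) {
  if (!file.exists(path)) stop("read_events: no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  ev <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"cs_type" %in% names(ev)) ev$cs_type <- "NONE"
  validate_events(ev, duration = duration, epoch_window = epoch_window)
}

#' Write an event table as delimited text
#' @param events events data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles the tunable settings of the pipeline: preprocessing filter bands,
#' mains-notch specification, smoothing, epoch window, dictionary latency
#' window and normalization. Defaults follow the published initial settings:
#' 28-250 Hz 4th-order Butterworth band-pass, 50 Hz notch, rectification, and
#' a 4th-order low-pass smoother with a 3 ms time constant (53.05 Hz cutoff).
#'
#' @param band band-pass cutoffs in Hz, `c(low, high)`.
#' @param band_order Butterworth design order of the band-pass.
#' @param notch_base mains base frequency (Hz).
#' @param notch_harmonics number of harmonics removed (clipped at Nyquist).
#' @param smooth_time_constant smoothing time constant in seconds; the implied
#'   low-pass cutoff is `1/(2*pi*tc)`.
#' @param smooth_order smoother design order.
#' @param epoch_window epoch length in seconds (half-open `[onset, onset+w)`).
#' @param latency_window dictionary latency window in seconds relative to zero,
#'   `c(lo, hi)` around the canonical onset; defaults to `x0 +/- (-0.02, 0.13)`
#'   once a response function is chosen.
#' @param sound_delay_sd standard deviation (s) of the measured sound-onset
#'   delay; when positive the latency window is expanded by twice this value
#'   on both sides.
#' @param normalize z-score single-trial estimates within subject.
#' @param amplitude_definition `"peak"` (signed value at the point of maximal
#'   absolute deviation) or `"area"` (signed integral) for multi-component
#'   reconstructions.
#' @param direction filter application: `"zero_phase"` (forward-backward) or
#'   `"causal"`.
#' @param seed optional RNG seed recorded with the run.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(band = c(28, 250), band_order = 4,
                            notch_base = 50, notch_harmonics = 5,
                            smooth_time_constant = 0.003, smooth_order = 4,
                            epoch_window = 0.5,
                            latency_window = c(-0.02, 0.13),
                            sound_delay_sd = 0,
                            normalize = FALSE,
                            amplitude_definition = c("peak", "area"),
                            direction = c("zero_phase", "causal"),
                            seed = NULL) {
  amplitude_definition <- match.arg(amplitude_definition)
  direction <- match.arg(direction)
  cfg <- list(band = as.numeric(band), band_order = as.integer(band_order),
              notch_base = as.numeric(notch_base),
              notch_harmonics = as.integer(notch_harmonics),
              smooth_time_constant = as.numeric(smooth_time_constant),
              smooth_order = as.integer(smooth_order),
              epoch_window = as.numeric(epoch_window),
              latency_window = as.numeric(latency_window),
              sound_delay_sd = as.numeric(sound_delay_sd),
              normalize = isTRUE(normalize),
              amplitude_definition = amplitude_definition,
              direction = direction, seed = seed)
  class(cfg) <- "analysis_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (length(cfg$band) != 2L || !all(is.finite(cfg$band)) ||
      cfg$band[1] <= 0 || cfg$band[1] >= cfg$band[2])
    stop("analysis_config: band must satisfy 0 < low < high")
  if (cfg$epoch_window <= 0)
    stop("analysis_config: epoch_window must be positive")
  if (cfg$smooth_time_constant <= 0)
    stop("analysis_config: smooth_time_constant must be positive")
  if (length(cfg$latency_window) != 2L ||
      cfg$latency_window[1] > cfg$latency_window[2])
    stop("analysis_config: latency_window bounds out of order")
  if (cfg$sound_delay_sd < 0)
    stop("analysis_config: sound_delay_sd must be >= 0")
  cfg
}

#' Read an analysis configuration from YAML or JSON
#'
#' Keys mirror the arguments of [analysis_config()]; nested keys
#' `preprocess.band`, `preprocess.notch = {base, harmonics}` and
#' `preprocess.smooth = {time_constant, order}` are also accepted. Unknown
#' keys are rejected.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: no such file: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$preprocess)) {
    pp <- raw$preprocess
    if (!is.null(pp$band)) raw$band <- unlist(pp$band)
    if (!is.null(pp$notch)) {
      if (!is.null(pp$notch$base)) raw$notch_base <- pp$notch$base
      if (!is.null(pp$notch$harmonics)) raw$notch_harmonics <- pp$notch$harmonics
    }
    if (!is.null(pp$smooth)) {
      if (!is.null(pp$smooth$time_constant))
        raw$smooth_time_constant <- pp$smooth$time_constant
      if (!is.null(pp$smooth$order)) raw$smooth_order <- pp$smooth$order
    }
    raw$preprocess <- NULL
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("read_config: unknown key(s): ", paste(unknown, collapse = ", "))
  raw$latency_window <- if (!is.null(raw$latency_window))
    unlist(raw$latency_window) else c(-0.02, 0.13)
  raw$band <- if (!is.null(raw$band)) unlist(raw$band) else c(28, 250)
  do.call(analysis_config, raw)
}

#' Write an amplitude table as delimited text
#'
#' Columns: `subject_id`, `method`, `scope`, `condition`, `trial_index`,
#' `amplitude` and, for the latency-estimating methods, `latency`.
#'
#' @param table amplitude table (data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_amplitudes <- function(table, path) {
  utils::write.table(table, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an amplitude table written by [write_amplitudes()]
#' @param path file path.
#' @return data.frame.
#' @export
read_amplitudes <- function(path) {
  if (!file.exists(path)) stop("read_amplitudes: no such file: ", path)
  utils::read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
}
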