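#' @title Peak-scoring methods B1, Br, G1, G2
#' @description Four published model-free startle quantification schemes.
#'   Each applies its own preprocessing chain to the raw EMG, then scores
#'   every trial as the maximum of the rectified-smoothed signal inside a
#'   fixed post-onset response window, minus (except G2) the mean over a
#'   baseline window. Windows are half-open `[start, end)` in seconds
#'   relative to the measured sound onset. Scores of the baseline-corrected
#'   methods may be negative; G2 scores are nonnegative by construction.
#' @name peak_scoring
NULL

# max over [w[1], w[2]) minus mean over baseline [b[1], b[2]) (NULL = none)
window_score <- function(rec, onset, response_window, baseline_window) {
  rate <- rec$sampling_rate
  on <- onset_sample(onset, rate)
  widx <- function(w) {
    lo <- on + round(w[1] * rate) + 1L
    hi <- on + round(w[2] * rate)
    if (lo < 1L || hi > length(rec$samples))
      stop(sprintf("peak scoring: window [%g, %g) s at onset %g s lies outside the recording",
                   w[1], w[2], onset))
    lo:hi
  }
  score <- max(rec$samples[widx(response_window)])
  if (!is.null(baseline_window))
    score <- score - mean(rec$samples[widx(baseline_window)])
  score
}

score_windows <- function(rec, events, method, response_window,
                          baseline_window) {
  events <- validate_events(events, duration = duration(rec))
  amps <- vapply(events$sound_onset, function(on)
    window_score(rec, on, response_window, baseline_window), numeric(1))
  out <- amplitude_rows(rec$subject_id, method, "trial", events$cs_type,
                        events$trial_index, amps)
  rbind(out, condition_means(out))
}

#' Peak scoring method B1
#'
#' Chain: 28-250 Hz 4th-order Butterworth band-pass, 50 Hz harmonics notch,
#' rectification, 20 ms moving average. Score: maximum in 20-120 ms after
#' sound onset minus the mean over the 20 ms window immediately before onset.
#'
#' @param rec raw [emg_recording()].
#' @param events validated events for this subject.
#' @param config an [analysis_config()] (supplies the notch harmonic count
#'   and filter direction).
#' @return amplitude table with per-trial rows and condition means.
#' @export
score_b1 <- function(rec, events, config = analysis_config()) {
  rec <- bandpass_filter(rec, 28, 250, order = 4,
                         direction = config$direction)
  rec <- notch_filter(rec, base = config$notch_base,
                      n_harmonics = config$notch_harmonics,
                      direction = config$direction)
  rec <- rectify(rec)
  rec <- smooth_moving_average(rec, 0.02)
  score_windows(rec, events, "B1", c(0.02, 0.12), c(-0.02, 0))
}

#' Peak scoring method Br
#'
#' Chain: 28 Hz 4th-order Butterworth high-pass, rectification, 30 Hz
#' 4th-order Butterworth low-pass. Score: maximum in 20-120 ms after onset
#' minus the mean over a 50 ms pre-onset baseline.
#'
#' @inheritParams score_b1
#' @return amplitude table.
#' @export
score_br <- function(rec, events, config = analysis_config()) {
  rec <- highpass_filter(rec, 28, order = 4, direction = config$direction)
  rec <- rectify(rec)
  rec <- lowpass_filter(rec, 30, order = 4, direction = config$direction)
  score_windows(rec, events, "Br", c(0.02, 0.12), c(-0.05, 0))
}

#' Peak scoring method G1
#'
#' Chain: 1-490 Hz 4th-order Butterworth band-pass, 50 Hz harmonics notch,
#' rectification, 20 ms moving average. Score: maximum in 21-120 ms after
#' onset minus the mean over the first 20 ms after onset. The post-onset
#' baseline may overlap early response activity; that is inherent to the
#' published method and reproduced literally.
#'
#' @inheritParams score_b1
#' @return amplitude table.
#' @export
score_g1 <- function(rec, events, config = analysis_config()) {
  rec <- bandpass_filter(rec, 1, 490, order = 4, direction = config$direction)
  rec <- notch_filter(rec, base = config$notch_base,
                      n_harmonics = config$notch_harmonics,
                      direction = config$direction)
  rec <- rectify(rec)
  rec <- smooth_moving_average(rec, 0.02)
  score_windows(rec, events, "G1", c(0.021, 0.12), c(0, 0.02))
}

#' Peak scoring method G2
#'
#' Chain: 30-490 Hz 4th-order Butterworth band-pass, 50 Hz harmonics notch,
#' rectification, 20 ms moving average. Score: maximum in 20-100 ms after
#' onset; no baseline subtraction.
#'
#' @inheritParams score_b1
#' @return amplitude table.
#' @export
score_g2 <- function(rec, events, config = analysis_config()) {
  rec <- bandpass_filter(rec, 30, 490, order = 4,
                         direction = config$direction)
  rec <- notch_filter(rec, base = config$notch_base,
                      n_harmonics = config$notch_harmonics,
                      direction = config$direction)
  rec <- rectify(rec)
  rec <- smooth_moving_average(rec, 0.02)
  score_windows(rec, events, "G2", c(0.02, 0.10), NULL)
}
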