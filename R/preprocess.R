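#' @title EMG preprocessing: filtering, rectification, smoothing
#' @description Stages that turn raw orbicularis oculi EMG into the rectified,
#'   smoothed envelope all amplitude estimators consume. All Butterworth
#'   stages are applied zero-phase (forward-backward) by default so that no
#'   group delay biases latency estimation; `direction = "causal"` switches to
#'   a single forward pass.
#' @name preprocess
NULL

nyquist <- function(rec) rec$sampling_rate / 2

apply_iir <- function(rec, filt, direction) {
  x <- rec$samples
  y <- if (direction == "zero_phase") signal::filtfilt(filt, x)
       else as.numeric(signal::filter(filt, x))
  rec$samples <- as.numeric(y)
  rec
}

#' Band-pass filter an EMG recording
#'
#' Butterworth band-pass of the stated design order. Note that forward-
#' backward application (the default) doubles the effective attenuation; the
#' order argument refers to the designed filter.
#'
#' @param rec an [emg_recording()].
#' @param low,high cutoff frequencies in Hz, `0 < low < high < Nyquist`.
#' @param order design order (default 4).
#' @param direction `"zero_phase"` or `"causal"`.
#' @return filtered recording, same length and rate.
#' @export
bandpass_filter <- function(rec, low, high, order = 4,
                            direction = c("zero_phase", "causal")) {
  direction <- match.arg(direction)
  nyq <- nyquist(rec)
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("bandpass_filter: need 0 < low < high < Nyquist (%g Hz); got [%g, %g]",
                 nyq, low, high))
  filt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  rec <- apply_iir(rec, filt, direction)
  add_provenance(rec, "bandpass", low = low, high = high, order = order,
                 direction = direction)
}

#' High-pass filter an EMG recording
#' @inheritParams bandpass_filter
#' @param cutoff cutoff frequency in Hz.
#' @return filtered recording.
#' @export
highpass_filter <- function(rec, cutoff, order = 4,
                            direction = c("zero_phase", "causal")) {
  direction <- match.arg(direction)
  nyq <- nyquist(rec)
  if (!(cutoff > 0 && cutoff < nyq))
    stop("highpass_filter: cutoff must lie in (0, Nyquist)")
  filt <- signal::butter(order, cutoff / nyq, type = "high")
  rec <- apply_iir(rec, filt, direction)
  add_provenance(rec, "highpass", cutoff = cutoff, order = order,
                 direction = direction)
}

#' Low-pass filter an EMG recording
#' @inheritParams highpass_filter
#' @return filtered recording.
#' @export
lowpass_filter <- function(rec, cutoff, order = 4,
                           direction = c("zero_phase", "causal")) {
  direction <- match.arg(direction)
  nyq <- nyquist(rec)
  if (!(cutoff > 0 && cutoff < nyq))
    stop("lowpass_filter: cutoff must lie in (0, Nyquist)")
  filt <- signal::butter(order, cutoff / nyq, type = "low")
  rec <- apply_iir(rec, filt, direction)
  add_provenance(rec, "lowpass", cutoff = cutoff, order = order,
                 direction = direction)
}

# RBJ-cookbook 2nd-order notch biquad at f0 with quality factor q
notch_biquad <- function(f0, rate, q) {
  w0 <- 2 * pi * f0 / rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  signal::Arma(b = b, a = a)
}

#' Remove mains hum and its harmonics
#'
#' Cascaded narrow 2nd-order IIR notches (quality factor `q`, default 35) at
#' `base`, `2*base`, ... up to `n_harmonics` or the Nyquist frequency,
#' whichever comes first; harmonics at or above Nyquist are skipped with a
#' warning.
#'
#' @inheritParams bandpass_filter
#' @param base mains base frequency in Hz (must be below Nyquist).
#' @param n_harmonics number of harmonics to notch (including the base).
#' @param q notch quality factor (centre frequency / -3 dB bandwidth).
#' @return filtered recording.
#' @export
notch_filter <- function(rec, base = 50, n_harmonics = 5, q = 35,
                         direction = c("zero_phase", "causal")) {
  direction <- match.arg(direction)
  nyq <- nyquist(rec)
  if (base >= nyq)
    stop("notch_filter: base frequency must be below Nyquist")
  freqs <- base * seq_len(n_harmonics)
  skipped <- freqs[freqs >= nyq]
  if (length(skipped))
    warning("notch_filter: skipping harmonic(s) at/above Nyquist: ",
            paste(skipped, collapse = ", "), " Hz")
  freqs <- freqs[freqs < nyq]
  for (f0 in freqs)
    rec <- apply_iir(rec, notch_biquad(f0, rec$sampling_rate, q), direction)
  add_provenance(rec, "notch", base = base, harmonics = freqs, q = q,
                 direction = direction)
}

#' Rectify an EMG recording
#'
#' Pointwise absolute value; idempotent.
#' @param rec an [emg_recording()].
#' @return rectified (nonnegative) recording.
#' @export
rectify <- function(rec) {
  rec$samples <- abs(rec$samples)
  add_provenance(rec, "rectify")
}

#' Time constant to low-pass cutoff
#'
#' A first-order smoothing time constant `tc` corresponds to the cutoff
#' `1/(2*pi*tc)`; 3 ms maps to 53.05 Hz.
#' @param time_constant time constant in seconds.
#' @return cutoff frequency in Hz.
#' @export
time_constant_to_cutoff <- function(time_constant) 1 / (2 * pi * time_constant)

#' Smooth a rectified EMG with a Butterworth low-pass
#'
#' The cutoff is derived from the time constant via
#' [time_constant_to_cutoff()]; the default 3 ms yields 53.05 Hz.
#'
#' @inheritParams bandpass_filter
#' @param time_constant smoothing time constant in seconds.
#' @return smoothed recording; the implied cutoff is recorded in provenance.
#' @export
smooth_lowpass <- function(rec, time_constant = 0.003, order = 4,
                           direction = c("zero_phase", "causal")) {
  direction <- match.arg(direction)
  if (time_constant <= 0) stop("smooth_lowpass: time_constant must be positive")
  cutoff <- time_constant_to_cutoff(time_constant)
  if (cutoff >= nyquist(rec))
    stop(sprintf("smooth_lowpass: implied cutoff %.2f Hz is at/above Nyquist",
                 cutoff))
  filt <- signal::butter(order, cutoff / nyquist(rec), type = "low")
  rec <- apply_iir(rec, filt, direction)
  add_provenance(rec, "smooth_lowpass", time_constant = time_constant,
                 cutoff = cutoff, order = order, direction = direction)
}

#' Smooth with a centred moving average
#'
#' Moving mean over `round(window * rate)` samples, centred on each sample;
#' at the edges the window shrinks to the available samples (no zero padding),
#' so baselines near epoch edges are unbiased.
#'
#' @param rec an [emg_recording()].
#' @param window window length in seconds (at least one sample).
#' @return smoothed recording.
#' @export
smooth_moving_average <- function(rec, window = 0.02) {
  n <- round(window * rec$sampling_rate)
  if (n < 1) stop("smooth_moving_average: window shorter than one sample")
  x <- rec$samples
  len <- length(x)
  left <- floor((n - 1) / 2)
  right <- n - 1 - left
  cs <- cumsum(c(0, x))
  i <- seq_len(len)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, len)
  rec$samples <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  add_provenance(rec, "moving_average", window = window, n_samples = n)
}

#' Standard model preprocessing chain
#'
#' Band-pass, mains notch, rectification, low-pass smoothing -- the chain the
#' model-based estimators consume. Defaults reproduce the published initial
#' settings (28-250 Hz, 50 Hz notch, 3 ms smoothing).
#'
#' @param rec raw [emg_recording()].
#' @param config an [analysis_config()].
#' @return preprocessed recording with full provenance.
#' @export
preprocess_model <- function(rec, config = analysis_config()) {
  config <- validate_config(config)
  rec <- bandpass_filter(rec, config$band[1], config$band[2],
                         order = config$band_order,
                         direction = config$direction)
  rec <- notch_filter(rec, base = config$notch_base,
                      n_harmonics = config$notch_harmonics,
                      direction = config$direction)
  rec <- rectify(rec)
  smooth_lowpass(rec, time_constant = config$smooth_time_constant,
                 order = config$smooth_order, direction = config$direction)
}
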