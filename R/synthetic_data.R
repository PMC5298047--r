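#' @title Synthetic EMG with known ground truth
#' @description Generator for surrogate startle eyeblink EMG: continuous
#'   recordings containing gamma-enveloped, band-limited noise bursts at
#'   randomized intertrial intervals, with lognormal trial-to-trial amplitude
#'   variability, Gaussian latency jitter, a multiplicative CS+ > CS-
#'   amplitude effect, band-limited background noise and optional mains hum.
#'   Every pipeline stage can thus be validated against per-trial ground
#'   truth without any recorded data.
#' @name synthetic_data
NULL

#' Simulation specification
#'
#' Defaults emulate the fear-retention startle protocol the model family was
#' validated on: 20 subjects, 20 CS+ and 20 CS- trials per subject in
#' randomized order, startle probes at intertrial intervals drawn uniformly
#' from 7-11 s (mean 9 s), 1 kHz sampling, probe 3.5 s after CS onset. The
#' response shape is the canonical gamma response function; trial amplitudes
#' are lognormal around the condition mean (`base_amplitude`, times
#' `cs_effect` for CS+), onset latencies are Gaussian around the canonical
#' onset (clamped to the dictionary latency window), and the burst rides on a
#' band-limited noise carrier.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_condition CS+ (= CS-) trials per subject.
#' @param sampling_rate Hz.
#' @param iti_range intertrial interval bounds in seconds (uniform draw).
#' @param base_amplitude mean CS- burst amplitude (microvolt scale of the
#'   unit-area gamma envelope).
#' @param cs_effect multiplicative CS+/CS- amplitude ratio (>= 0; 1 = null).
#' @param amplitude_cv coefficient of variation of trial amplitudes.
#' @param latency_jitter_sd SD of the trial onset latency around the
#'   canonical `x0`, seconds.
#' @param carrier_band burst carrier band in Hz.
#' @param noise_band background-noise band in Hz; defaults to broadband
#'   (1-490 Hz), the realistic regime for EMG amplifier and resting-muscle
#'   noise. Set equal to `carrier_band` to confine the noise to the burst
#'   band (in which case filter-band optimization has nothing to recover).
#' @param noise_sd background noise SD in microvolts.
#' @param mains_amplitude amplitude of an optional 50 Hz mains component
#'   (microvolts; 0 disables).
#' @param mains_freq mains frequency in Hz.
#' @param gamma canonical response parameters ([gamma_params()]).
#' @param epoch_window epoch length in seconds.
#' @param cs_lead seconds between CS onset and the startle probe.
#' @param seed master RNG seed (integer); per-subject streams are derived
#'   from it.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_subjects = 20, trials_per_condition = 20,
                            sampling_rate = 1000, iti_range = c(7, 11),
                            base_amplitude = 5, cs_effect = 2,
                            amplitude_cv = 0.5, latency_jitter_sd = 0.01,
                            carrier_band = c(30, 300),
                            noise_band = c(1, 490), noise_sd = 3,
                            mains_amplitude = 0, mains_freq = 50,
                            gamma = sebrf_presets$initial,
                            epoch_window = 0.5, cs_lead = 3.5, seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               trials_per_condition = as.integer(trials_per_condition),
               sampling_rate = sampling_rate, iti_range = as.numeric(iti_range),
               base_amplitude = base_amplitude, cs_effect = cs_effect,
               amplitude_cv = amplitude_cv,
               latency_jitter_sd = latency_jitter_sd,
               carrier_band = as.numeric(carrier_band),
               noise_band = as.numeric(noise_band), noise_sd = noise_sd,
               mains_amplitude = mains_amplitude, mains_freq = mains_freq,
               gamma = gamma, epoch_window = epoch_window, cs_lead = cs_lead,
               seed = as.integer(seed))
  stopifnot(spec$n_subjects >= 1, spec$trials_per_condition >= 1,
            spec$sampling_rate > 0, spec$cs_effect >= 0,
            spec$amplitude_cv >= 0, spec$latency_jitter_sd >= 0,
            spec$noise_sd >= 0, length(spec$iti_range) == 2,
            spec$iti_range[1] <= spec$iti_range[2])
  if (spec$iti_range[1] <= spec$epoch_window + 0.2)
    stop("simulation_spec: ITI shorter than the epoch window is infeasible")
  class(spec) <- "simulation_spec"
  spec
}

# band-limited unit-variance Gaussian noise; generated with padding so filter
# edge transients are discarded
band_limited_noise <- function(n, band, rate) {
  pad <- min(n, round(rate))
  x <- stats::rnorm(n + 2 * pad)
  nyq <- rate / 2
  filt <- signal::butter(4, pmin(band, nyq * 0.999) / nyq, type = "pass")
  y <- signal::filtfilt(filt, x)[(pad + 1):(pad + n)]
  y / stats::sd(y)
}

#' Simulate a single startle burst
#'
#' `amplitude * gamma envelope (onset at latency) * band-limited noise
#' carrier`. After rectification and smoothing, the expected envelope is
#' proportional to the gamma response function (scaled by E|carrier| =
#' sqrt(2/pi)).
#'
#' @param amplitude burst amplitude (>= 0).
#' @param latency onset latency in seconds (the gamma `x0` of this trial).
#' @param params canonical [gamma_params()] supplying shape and scale.
#' @param carrier_band carrier band in Hz.
#' @param rate sampling rate in Hz.
#' @param duration burst segment length in seconds.
#' @param epoch_window epoch length in seconds; a latency placing the bulk of
#'   the gamma (its 99.9% point) beyond this window is rejected.
#' @return numeric vector of `round(duration * rate)` samples. Uses the
#'   current RNG stream.
#' @export
simulate_trial_burst <- function(amplitude, latency, params,
                                 carrier_band = c(30, 300), rate = 1000,
                                 duration = 0.7, epoch_window = 0.5) {
  if (amplitude < 0) stop("simulate_trial_burst: amplitude must be >= 0")
  n <- round(duration * rate)
  grid <- (seq_len(n) - 1L) / rate
  tail999 <- stats::qgamma(0.999, shape = params$k, scale = params$theta)
  if (latency + tail999 > epoch_window)
    stop("simulate_trial_burst: latency pushes the burst outside the epoch")
  envelope <- gamma_rf(grid, gamma_params(params$k, params$theta, latency, 1))
  if (amplitude == 0) return(numeric(n))
  amplitude * envelope * band_limited_noise(n, carrier_band, rate)
}

#' Simulate a full multi-subject startle dataset
#'
#' Per subject, CS+ and CS- trials in randomized order at uniform ITIs, each
#' carrying one startle burst with lognormal amplitude and jittered latency,
#' on top of band-limited background noise and optional mains hum. Each
#' subject has an independent RNG stream derived from the master seed, so
#' regenerating one subject is stable under changes elsewhere.
#'
#' @param spec a [simulation_spec()].
#' @return list with `recordings` (named list of [emg_recording()]s),
#'   `events` (validated data.frame) and `ground_truth` (data.frame with
#'   per-trial true amplitude, latency and onset).
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  rate <- spec$sampling_rate
  lat_win <- dictionary_latency_window(spec$gamma)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_subjects)
  recordings <- list()
  events <- NULL
  truth <- NULL
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("s%02d", s)
    set.seed(subject_seeds[s])
    n_tr <- 2L * spec$trials_per_condition
    cs <- sample(rep(c("CSP", "CSM"), spec$trials_per_condition))
    itis <- stats::runif(n_tr, spec$iti_range[1], spec$iti_range[2])
    # first probe after cs_lead + 0.5 s settling, then uniform ITIs
    onsets <- spec$cs_lead + 0.5 + cumsum(c(0, itis[-1]))
    mean_amp <- spec$base_amplitude * ifelse(cs == "CSP", spec$cs_effect, 1)
    sdlog <- sqrt(log(1 + spec$amplitude_cv^2))
    amps <- stats::rlnorm(n_tr, meanlog = log(pmax(mean_amp, 1e-300)) -
                            sdlog^2 / 2, sdlog = sdlog)
    amps[mean_amp == 0] <- 0
    lats <- stats::rnorm(n_tr, spec$gamma$x0, spec$latency_jitter_sd)
    lats <- pmin(pmax(lats, lat_win[1]), lat_win[2])
    n_samp <- round((max(onsets) + 1.5) * rate)
    sig <- spec$noise_sd *
      band_limited_noise(n_samp, spec$noise_band, rate)
    if (spec$mains_amplitude > 0) {
      tgrid <- (seq_len(n_samp) - 1L) / rate
      sig <- sig + spec$mains_amplitude *
        sin(2 * pi * spec$mains_freq * tgrid + stats::runif(1, 0, 2 * pi))
    }
    burst_len <- 0.7
    for (i in seq_len(n_tr)) {
      burst <- simulate_trial_burst(amps[i], lats[i], spec$gamma,
                                    spec$carrier_band, rate,
                                    duration = burst_len)
      start <- onset_sample(onsets[i], rate) + 1L
      idx <- start:(start + length(burst) - 1L)
      sig[idx] <- sig[idx] + burst
    }
    recordings[[sid]] <- emg_recording(sig, rate, subject_id = sid)
    events <- rbind(events, data.frame(
      subject_id = sid, trial_index = seq_len(n_tr) - 1L,
      sound_onset = onsets, cs_onset = onsets - spec$cs_lead,
      cs_type = cs, us_delivered = FALSE, stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      subject_id = sid, trial_index = seq_len(n_tr) - 1L, condition = cs,
      true_amplitude = amps, true_latency = lats, sound_onset = onsets,
      stringsAsFactors = FALSE))
  }
  list(recordings = recordings,
       events = validate_events(events),
       ground_truth = truth, spec = spec)
}
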