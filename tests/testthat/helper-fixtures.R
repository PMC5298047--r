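# Shared fixtures: tiny recordings, event tables and simulations built in code.

# deterministic sine-mix recording
make_recording <- function(n = 2000, rate = 1000, freqs = c(40, 120),
                           amps = c(1, 0.5), subject_id = "s01") {
  t <- (seq_len(n) - 1) / rate
  x <- rowSums(sapply(seq_along(freqs), function(i)
    amps[i] * sin(2 * pi * freqs[i] * t)))
  emg_recording(x, rate, subject_id = subject_id)
}

make_events <- function(onsets, cs_type = rep("NONE", length(onsets)),
                        subject_id = "s01") {
  data.frame(subject_id = subject_id,
             trial_index = seq_along(onsets) - 1L,
             sound_onset = onsets,
             cs_onset = NA_real_,
             cs_type = cs_type,
             us_delivered = FALSE,
             stringsAsFactors = FALSE)
}

# small fast simulation: short ITIs keep recordings compact while preserving
# the trial structure (epoch 0.5 s + dictionary span fit comfortably in 2.5 s)
small_sim <- function(seed, n_subjects = 2, trials_per_condition = 5, ...) {
  simulate_dataset(simulation_spec(
    n_subjects = n_subjects, trials_per_condition = trials_per_condition,
    iti_range = c(2.5, 3.5), seed = seed, ...))
}

# steady-state RMS of the middle portion of a vector (discard edge transients)
mid_rms <- function(x, frac = 0.25) {
  n <- length(x)
  keep <- seq.int(floor(n * frac), ceiling(n * (1 - frac)))
  sqrt(mean(x[keep]^2))
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
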