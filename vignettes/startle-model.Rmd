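---
title: "Model-based analysis of startle eyeblink EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based analysis of startle eyeblink EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(startlemod)
```

## The model

The startle eyeblink response (SEBR) is the burst of orbicularis oculi EMG
elicited by a sudden loud probe. `startlemod` treats the rectified, smoothed
EMG as the output of a linear time-invariant (LTI) system: a delta input at
each probe onset, convolved with a fixed response function, plus noise,

$$y(t) = \sum_i a_i \, h(t - t_i) + \varepsilon(t),$$

where \(h\) is the canonical startle eyeblink response function (SEBRF), a
gamma density with shape \(k\), scale \(\theta\) (s), onset latency \(x_0\)
(s) and amplitude \(A\):

$$h(x) = \frac{A}{\theta^k\,\Gamma(k)}\,(x - x_0)^{k-1}
  e^{-(x - x_0)/\theta}, \qquad x > x_0 .$$

Its peak sits at \(x_0 + (k-1)\theta\), about 62 ms after probe onset for the
shipped canonical parameters (`sebrf_presets$initial`: \(k = 2.5320\),
\(\theta = 0.0154\), \(x_0 = 0.0383\)), with the response essentially over
within 500 ms. The per-trial (or per-condition) amplitudes \(a_i\) are the
quantity of scientific interest: in fear conditioning, probes presented
during a stimulus that predicts an aversive outcome (CS+) elicit larger
startle than during a safe stimulus (CS−), and the amplitude contrast
measures fear memory.

Six inversions of this forward model are provided:

* **M1** — the SEBRF alone, one regressor per condition, inverted as a
  general linear convolution model (GLM) via the Moore–Penrose
  pseudoinverse.
* **M2 / M2ST** — SEBRF plus its analytic time derivative
  (Gram–Schmidt-orthogonalised to the SEBRF), per condition or per trial.
  The derivative absorbs small latency variations.
* **M3** — SEBRF plus a Gaussian tail component (\(\mu = 0.2119\),
  \(\sigma = 0.1854\) s), capturing the slow tail the gamma misses.
* **M4 / M4ST** — the SEBRF with onset latency as a free parameter,
  estimated per condition or per trial by dictionary matching: among
  latency-shifted unit responses on a one-sample grid spanning
  \([x_0 - 0.02,\; x_0 + 0.13]\) s (expanded by twice the sound-onset-delay
  SD when probe timing was only approximately recorded), the element with
  the maximal signed inner product with the data is entered into the GLM.

Four published peak-scoring baselines (`score_b1`, `score_br`, `score_g1`,
`score_g2`) quantify each trial as the maximum of the rectified-smoothed
signal in a fixed post-onset window, with method-specific filter chains and
baseline corrections.

Methods are compared by *predictive validity*: a regression predicting CS
type (CS+ = 1, CS− = 0) from the amplitude estimate with subject-specific
intercepts; its residual sum of squares is converted to
\(\mathrm{AIC} = n \log(\mathrm{RSS}/n) + 2k\), and an absolute AIC
difference above 3 is treated as decisive (relative evidence below
\(e^{-3} \approx .05\)). With one CS+ and one CS− mean per subject, the
slope's \(t\) statistic is algebraically the paired \(t\) test on the
condition differences — the package property-tests this identity — and
Cohen's \(d = t/\sqrt{n}\).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| band-pass | 28–250 | Hz | pre-rectification Butterworth band (4th order) |
| notch | 50, 5 harmonics | Hz | mains removal (Q = 35 biquads) |
| smoothing time constant | 0.003 | s | envelope low-pass, cutoff \(1/(2\pi\tau)\) = 53.05 Hz |
| epoch window | 0.5 | s | half-open `[onset, onset + w)` |
| latency window | \(x_0\) + [−0.02, 0.13] | s | dictionary span, one-sample grid |
| amplitude definition | `"peak"` | — | signed value at the maximal absolute deviation of the reconstruction |

Optimized presets `optimized_m2st` (60–480 Hz band) and `optimized_m4st`
(50–470 Hz band) carry the refitted gamma parameters for those bands.

## Numerical choices

* **Zero-phase filtering.** All Butterworth stages run forward–backward by
  default. The source publications state bidirectional filtering only for
  other modalities; we choose zero-phase for EMG because a causal filter's
  group delay would bias exactly the latency the M4 family estimates. The
  stated order is the design order; forward–backward application doubles the
  effective attenuation. `direction = "causal"` switches to a single pass.
* **Notch realisation.** The bandwidth of the published 50 Hz notch is
  unspecified; we use 2nd-order biquads with Q = 35, which remove the mains
  line (measured response \(\sim 10^{-14}\) at 50 Hz) while leaving 80 Hz
  within 0.004 dB.
* **Baseline regressor.** Rectified EMG has a positive noise floor, so every
  inversion GLM includes a constant column; without it the floor leaks into
  the response betas.
* **PCA on uncentred epochs.** Whether the template derivation centred its
  epochs is unstated; we use uncentred PCA (plain SVD) so the first
  component tracks the mean burst shape, which is the object the gamma is
  fitted to. The PC1 sign is oriented so its peak is positive. Before
  fitting, the pre-onset level (first 20 ms) is subtracted from PC1 so the
  gamma is fitted to the burst, not the rectified noise floor.
* **Gamma fitting.** Nelder–Mead on \((\log k, \log\theta, x_0, A)\);
  start from a data-driven initialisation (onset at 10% of peak, shape 2,
  scale from the peak time, amplitude from the area) plus deterministic
  perturbed restarts, keeping the best residual sum of squares; the fit is
  never returned worse than its initialisation. The M3 tail is a unit-peak
  Gaussian whose free scale is absorbed by its regression coefficient after
  orthogonalisation — whether the original tail had its own fitted amplitude
  is not documented, and this convention makes the choice immaterial.
* **"Signed absolute variation from zero."** For multi-component
  reconstructions the amplitude is the signed value of the reconstruction at
  the point of maximal absolute deviation within the epoch (the reading
  consistent with the analogous peak-deviation definition used for heart
  period responses); a signed-area alternative sits behind
  `amplitude_definition = "area"`.
* **Dictionary conventions.** Rows have unit amplitude (not unit norm) so
  the estimates share the canonical scale; ranking by signed inner product
  is unaffected by a common positive scale. Ties break toward the earliest
  latency. Per-condition matching (M4) maximises the inner product summed
  across the condition's trials — summing versus averaging cannot change the
  ranking. The matching segment extends the epoch by the latency span above
  the canonical onset so late candidates are fully observed; with a
  width-zero window the M4 estimate equals M1 exactly (tested).
* **Tie-breaks in the filter search** go to the lowest high-pass, then the
  lowest low-pass cutoff, so results are deterministic.
* The Methods description of the published low-pass search range (200–490
  Hz) disagrees with the Results narrative (20–490 Hz); the Methods range is
  the default grid (9 × 30 = 270 cells) and either can be passed explicitly.

## The synthetic generator

`simulate_dataset()` emulates a fear-retention startle session: per subject,
randomized CS+/CS− trials with probes at intertrial intervals uniform on
7–11 s (mean 9 s), 1 kHz sampling, probe 3.5 s after CS onset. Each trial
contributes `amplitude × gamma envelope × band-limited noise carrier`
(default carrier 30–300 Hz) — after rectification and smoothing the expected
envelope is proportional to the SEBRF. Trial amplitudes are lognormal around
the condition mean (CS− mean 5 µV-scale, CS+ mean multiplied by
`cs_effect = 2`, a robust fear-potentiation effect; CV 0.5, reflecting the
strong right-skewed trial-to-trial variability of real startle magnitudes);
onset latencies are Gaussian around \(x_0\) (SD 10 ms) clamped — not
rejection-sampled — to the dictionary window; background noise is broadband
(1–490 Hz, SD 3 µV), the realistic regime for amplifier and resting-muscle
noise, and a 50 Hz mains component can be added. Each subject has an
independent RNG stream derived from the master seed.

What the generator does **not** emulate: habituation or extinction dynamics
across trials, non-responders, movement artifacts, electrode drift, or
overlapping responses (prepulse paradigms violate the LTI summation
assumption and are out of scope). Passing tests therefore demonstrate
correct inversion of the assumed generative model at realistic noise levels,
not robustness to every artifact of recorded EMG.

## Validation design and problem sizes

The test suite validates the pipeline end to end at sizes chosen to keep a
full run comfortably reproducible on one CPU:

* Gamma parameter recovery: 50 noisy fits at 5% of peak noise; median
  relative error per parameter below 10%.
* Single-trial recovery: at default noise, M4ST amplitude estimates
  correlate with ground truth above 0.7 (50 trials per seed) and median
  latency error stays below 5 ms.
* Effect detection: a 2× CS+ effect with 20 trials per condition is
  detected (mean CS+ > mean CS−) in at least 95 of 100 seeds.
* Calibration: paired-t type-I error over 1000 null draws stays inside the
  binomial band around 5%; AIC differences are exactly invariant to affine
  rescaling of any method's amplitudes.
* Filter-band search: the full published grid has 270 cells; the recovery
  experiment runs a scaled-down 2 × 2 grid (high-pass 30/250, low-pass
  120/350 Hz) on 10 subjects × 8 trials per condition with shortened
  intertrial intervals (2.5–3.5 s), bursts generated in a 60–300 Hz carrier
  band with band-confined background noise, low biological amplitude
  variability (CV 0.1) and a noise-limited amplitude (0.5). These
  conditions isolate the filter's contribution: band recovery by predictive
  validity is identifiable only when estimation noise, not biological
  variability, limits discrimination — biological variability scales with
  the filter's attenuation exactly as the condition effect does and cancels
  out of the comparison. Under broadband background noise a further effect
  appears that is worth knowing about when optimizing filters on real data:
  noise below the ~53 Hz envelope smoother passes directly into the
  envelope, which rewards high-pass cutoffs *inside* the burst band. The
  winning cell then legitimately excludes part of the generating band — a
  property of rectify-then-smooth pipelines generally, not an artifact.

## Known limitations

* The canonical parameters are shipped constants; re-deriving them requires
  the original human recordings, which are not distributable.
* Latency clamping slightly inflates density at the dictionary-window edges
  relative to a truncated normal.
* The LTI assumption precludes overlapping-response designs (prepulse
  inhibition); no deconvolution of overlapping bursts is attempted.
* Peak scorers reproduce their published definitions literally, including
  G1's post-onset baseline window, which can overlap early response
  activity.

## A minimal session

```{r example, eval = FALSE}
sim <- simulate_dataset(simulation_spec(n_subjects = 4,
                                        trials_per_condition = 5, seed = 1))
m4st <- estimate_dataset(sim$recordings, sim$events, "M4ST",
                         params = sebrf_presets$initial)
b1 <- estimate_dataset(sim$recordings, sim$events, "B1")
compare_methods(list(M4ST = m4st, B1 = b1))
```
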