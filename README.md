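# rivalinfo

Information dynamics of bistable perception from EEG and optokinetic
nystagmus (OKN), in R.

When a bistable stimulus (e.g. an ambiguous moving plaid) is viewed, its
interpretation alternates between one *integrated* object (INT) and two
*differentiated* objects (DIF). The slow phase of OKN follows the
*perceived* motion, so the sign of slow-phase eye velocity reports the
current percept without a button press — a no-report readout of
perception. `rivalinfo` implements the analysis chain built on that idea:

* **OKN processing** — blink interpolation, zero-phase Butterworth
  filtering, deconvolution-based removal of blink/saccade responses,
  percent-signal-change scaling, slow-phase velocity (100-ms Gaussian
  smoothing, first difference, smoothing again), and switch detection as
  debounced, hysteresis-guarded velocity zero-crossings; gamma fits to
  dominance durations; OKN-to-button-press delay contrasts.
* **A convolutional decoder** of the upcoming percept from single
  1.25-s velocity epochs (conv 8@1×25 → pool → conv 16@2×50 → pool →
  conv 32@2×75 → dense-2 softmax; SGD with momentum 0.9, batch 128,
  cross-entropy), with stratified 70/15/15 splits and
  cross-classification between labelling schemes.
* **Directed information** (transfer entropy) between anterior and
  posterior EEG regions of interest, delay-resolved:
  `dirINFO(t, τ) = I(Y_t ; X_{t−τ} | Y_{t−τ})`, estimated across epochs
  by Gaussian-copula conditional mutual information (rank-normalize to
  normal quantiles, then covariance-determinant CMI in bits).
* **Signal differentiation** — compression complexity: 32-symbol
  amplitude binning per 100-ms window, DEFLATE compression, ratio of
  compressed to original size, sliding at 4-ms steps.
* **Time-frequency power** — complex Morlet wavelets, 2–26 Hz in 2-Hz
  steps with 3–12 log-spaced cycles, dB-normalized to the full-epoch
  baseline.
* **Cluster-based permutation statistics** — paired t maps, suprathreshold
  clustering (1-D neighbours / 2-D 4-connectivity), summed-t cluster mass
  against a max-statistic sign-flip null, and double-subtraction
  interaction contrasts.
* **A ground-truthed synthetic-session generator** — gamma-distributed
  dominance durations, OKN traces with blinks and fast-phase resets, and
  multichannel EEG with lagged anterior→posterior coupling and gated
  low-frequency oscillations, so the whole pipeline is testable without
  recorded data.

## Worked example

Generate a clean synthetic session, recover the perceptual switches from
the eye trace, and locate the injected 100-ms feedback coupling in the
EEG:

```r
library(rivalinfo)

cfg <- sim_config(seed = 1, fast_phase_rate = 0, blink_rate = 0)
ses <- synth_session(cfg)

vel <- slow_phase_velocity(lowpass_filter(interpolate_blinks(ses$okn)))
switches <- detect_switches(vel)
truth <- switch_directions(ses$schedule)
mean(sapply(truth$time, function(t) min(abs(switches$time - t))) <= 0.1)
#> [1] 1

ei <- synth_epochs(32, "to_INT", sim_config(seed = 2), window = c(-800, 100))
map <- directed_information(ei$front, ei$back,
                            delays = seq(0, 200, 4),
                            times = seq(-600, 0, 20))
map
#> <delay_time_map> front->back [to_INT]: 51 delays x 31 times, 32 epochs
```

The first number is switch-detection recall within ±100 ms on the clean
session (here every scheduled switch is recovered). The map holds directed
information in bits per (delay, time) cell; averaged over subjects, its
INT−DIF difference peaks at the generator's 100-ms coupling delay inside
the pre-switch modulation window, and the cluster permutation test on the
subject maps marks that region significant in the feedback
(front→back) direction only.

## Documentation

The methods vignette (`vignettes/information-dynamics.Rmd`) describes the
generative model behind the synthetic sessions, every estimator and its
numerical edge cases, the tunable parameters with their defaults and
rationale, and what passing the synthetic-data tests does and does not
demonstrate about recorded data.
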