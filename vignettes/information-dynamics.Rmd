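---
title: "Information dynamics of bistable perception: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information dynamics of bistable perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivalinfo)
```

## The analysis problem

When observers view an ambiguous moving-plaid stimulus, perception
alternates spontaneously between a single coherently moving object (the
*integrated* percept, INT) and two objects sliding across one another (the
*differentiated* percept, DIF). Because the slow phase of optokinetic
nystagmus (OKN) tracks the perceived — not the physical — motion
direction, the sign of slow-phase eye velocity reports the current percept
without any button press. `rivalinfo` implements the full analysis chain
around this idea:

1. **okn** — turn raw oculomotor traces into slow-phase velocity and
   detect perceptual switches as velocity zero-crossings;
2. **decoder** — a small convolutional network that classifies the
   upcoming percept from single velocity epochs;
3. **infodyn** — delay-resolved directed information (transfer entropy)
   between anterior and posterior EEG regions, and compression-based
   signal differentiation within a region;
4. **spectral** — Morlet time-frequency power with decibel baseline
   normalization;
5. **stats** — cluster-based permutation inference for paired contrasts
   and double-subtraction interactions;
6. **core_io** — EEG preprocessing, epoch cutting/rejection and text I/O;
7. **syndata** — a ground-truthed generator that emulates the signal
   structure all of the above assume, so every stage is testable without
   recorded data.

## The synthetic-session generator

The generator is first-class, tested code, and its defaults define the
conditions under which the package validates itself.

**Percept schedule.** Dominance durations are gamma distributed. Published
datasets in this paradigm report the gamma shape only qualitatively, so the
defaults (shape 3, scale 2 s — mean dominance 6 s) are conventional values
for visual rivalry, chosen once. Labels alternate strictly.

**OKN trace** (500 Hz). The slow-phase slope is `-okn_slow_speed` during
INT and `+okn_slow_speed` during DIF, with a logistic slope reversal of
400 ms width around each switch — resembling the gradual crossings seen in
real traces. Superimposed are instantaneous fast-phase resets (Poisson,
2 Hz), blink gaps (Poisson, 0.2 Hz, 100–300 ms, samples set to `NA` — a
dedicated missing sentinel, never an extreme value, so interpolation is
unambiguous) and Gaussian sensor noise.

**EEG** (250 Hz, 24 channels over four 6-channel ROIs). Every channel
carries 1/f background noise. Anterior channels share a white latent
source $A(t)$; posterior channels receive $g(t)\,A(t-\delta)$ with
$\delta = 100$ ms. The gain $g$ is 1.0 inside the 600 ms window before a
switch to INT, 0.2 before a switch to DIF, and 0.2 elsewhere — the minimal
additive structure that reproduces the reported direction of the effect
(stronger front-to-back information transfer before integrated percepts).
The latent is white rather than 1/f so the coupling is concentrated at a
single lag and delay recovery can be scored sharply; the background keeps
the 1/f appearance of the channels. Anterior channels additionally receive
a 4 Hz oscillation gated by the same windows, with amplitude 3 (in
background-SD units) before INT and 0 before DIF. The oscillation raises
low-frequency power and *lowers* compression complexity in the same
window, which reproduces the reported negative power–complexity relation;
the amplitude default was set so that the complexity effect is resolvable
by 100-ms windows, since DEFLATE on 25-sample windows is dominated by
container overhead and responds only weakly to smooth components.

`synth_epochs()` generates switch-locked ROI-averaged epochs directly with
the identical structure — orders of magnitude cheaper than cutting epochs
out of full sessions, which matters for the calibration studies.
`null_config()` equalizes all gated parameters across conditions, making
the two condition labels exchangeable by construction; it is the
ground truth for type-I calibration.

**What the generator does not emulate:** volume conduction and sensor
covariance structure, non-stationary artifacts (drift, muscle), the
tristable depth-order ambiguity of real plaids, saccadic intrusions during
smooth pursuit, and any biophysical forward model. Passing tests therefore
demonstrate correctness of the estimators and inference machinery under
the stated statistical structure, not performance on recorded data.

## OKN processing

The preprocessing follows the standard pupil/OKN chain: (i) linear
interpolation across blinks ±150 ms; (ii) zero-phase 3rd-order Butterworth
low-pass at 10 Hz; (iii) estimation of blink- and saccade-locked responses
by least-squares deconvolution (shifted-indicator design matrix; the
default 0–6 s window follows the pupil-response literature) and their
removal by regression; (iv) conversion to percent signal change around the
block mean. All filtering is forward–backward so crossing times carry no
filter latency; the implementation reflects the signal about its endpoints
before filtering because plain forward–backward filtering leaves large
end transients.

Slow-phase velocity is the first difference of the Gaussian-smoothed
trace, smoothed again with the same kernel. "100 ms kernel" is interpreted
as full width at half maximum (SD = 100/2.355 ms); `width_is_fwhm = FALSE`
switches to the SD reading. Velocity is reported per sample step, so a
ramp of $a$ units/s at 500 Hz gives $0.002a$ per step. The first and last
three kernel SDs are flagged unreliable rather than trimmed.

Switch detection is a hysteresis state machine over velocity sign runs: a
crossing is accepted only if it flips the confirmed state, the following
excursion exceeds the hysteresis (default 10% of the velocity SD), and it
is either ≥ 0.5 s after the previous accepted crossing or followed by a
sign run that itself persists ≥ 0.5 s — a persistent reversal is a real
switch even when it arrives quickly, and dropping it would leave the
state machine permanently out of phase. The hysteresis and separation
defaults are design choices, since no published values exist. Acceptance
only on state flips guarantees strict direction alternation. Under the default
polarity a positive-to-negative crossing marks `to_INT`; the flag
`int_positive` covers runs with the opposite stimulus drift, which
alternated between runs in the experimental design this emulates.

## The decoder

The network reproduces the published architecture exactly: input 1 × 625
(1.25 s of velocity at 500 Hz, epoch placed symmetrically around the
crossing — the placement is unstated in the source description, so
symmetric is the default), conv 8 @ 1 × 25 (ReLU, stride 1), maxpool 1 × 5
stride 2, conv 16 @ 2 × 50, maxpool 1 × 5 stride 2, conv 32 @ 2 × 75,
dense 2 with softmax; SGD with momentum 0.9, batch 128, 30 epochs,
validation every 10 mini-batches, cross-entropy loss; 97,474 parameters.

The printed kernel shapes 2 × 50 and 2 × 75 are dimensionally ambiguous on
a one-channel signal. The default resolves them as genuine 2-D
convolutions over (feature map, time): after the first pooling stage the 8
maps are stacked as the height axis of a single-channel image, so a 2 × 50
kernel spans pairs of adjacent maps. A 1-D fallback (`conv_mode = "1d"`,
kernels 50 and 75 across all input maps) is provided and is roughly an
order of magnitude cheaper; the test suite uses it for multi-seed
controls. The learning rate is unstated in the source; the default is
0.01. No early stopping is used — a fixed number of epochs. Inputs should
be standardized to unit SD; raw velocity units are ~10⁻³ per step, which
stalls gradient descent. Splits are stratified 70/15/15 by
largest-remainder allocation within class, so 1000 balanced epochs give
exactly 700/150/150 with 350/75/75 per class.

Forward and backward passes are written as im2col gathers plus BLAS matrix
products; training is deterministic given the seeds (Glorot-uniform
initialization and epoch shuffling are the only random elements). The
test suite trains on reduced problem sizes (400 epochs, 2 training epochs
for the full architecture; 200 epochs, 3 training epochs for the 1-D
variant), which suffice because the clean task is linearly separable — a
logistic baseline on late-minus-early velocity reaches the same ≥ 0.95
accuracy, which is what licenses the threshold.

## Directed information

For sender $X$ and receiver $Y$ (ROI-averaged EEG), at evaluation time $t$
and delay $\tau$:

$$\mathrm{dirINFO}(t, \tau) = I\!\left(Y_t;\, X_{t-\tau} \mid Y_{t-\tau}\right)$$

estimated across epochs by the Gaussian-copula method: each of the three
variables is rank-transformed to standard-normal quantiles
($\Phi^{-1}((r-0.5)/n)$, ties broken by stable order with a warning), then
the Gaussian CMI is computed from covariance determinants,
$I = \tfrac12 \log_2 \frac{|\Sigma_{xz}||\Sigma_{yz}|}{|\Sigma_z||\Sigma_{xyz}|}$.
The estimator is the one the robust-estimation literature attaches to this
measure; the source description never names its estimator explicitly, so
this is recorded as an interpretation, as is the choice of bits (log 2) as
the unit. Whether estimation ran across pooled trials or per trial is also
unstated; across-epoch estimation per subject is implemented because the
rank transform requires a sample per $(t, \tau)$ cell.

Numerical details: at $\tau = 0$ the conditioner duplicates $Y_t$ and the
determinant ratio is 0/0; these cells are defined as 0 (conditioning on
the variable itself leaves no information). Cells with $t - \tau$ before
the epoch start are `NA` and excluded from statistics, never zero-filled.
The plug-in estimator carries a positive small-sample bias that is
constant at fixed $n$; `bias_correct = TRUE` subtracts the expected
Wishart log-determinant bias. The default is off, matching the plug-in
convention; condition differences cancel the bias exactly, which is why
the recovery analyses report INT−DIF difference maps. Copula normalization
makes all maps invariant under strictly monotone amplitude transforms of
either signal.

The default grid is delays 0–500 ms in 4 ms steps over the −2000…500 ms
epoch. The validation studies use delays 0–200 ms and evaluation times
every 20 ms, which keeps a 10-replicate group study (12 subjects × 64
epochs × 2 conditions × 2 directions) inside a few minutes on one CPU
while leaving the 4 ms resolution around the true delay intact.

## Signal differentiation (compression complexity)

Each 100-ms window is symbolized into 32 equal-width amplitude bins
spanning the window's own range (per-window rather than per-channel
binning keeps the measure local and affine-invariant; per-epoch range is
available via the arguments), the symbol bytes are DEFLATE-compressed at
the default level 6, and the complexity is compressed size over original
size. The fixed 6 bytes of zlib container wrapper are excluded so ratios
are comparable across window lengths; ratios can exceed 1 for short
incompressible windows. Windows slide in 4 ms steps by default; the window
count is $\lfloor (L - w)/s \rfloor + 1$. Complexity is computed per epoch
and averaged per condition.

## Spectral analysis

Complex Morlet wavelets (Gaussian-windowed complex exponentials, temporal
SD $\zeta = c/(2\pi f)$) on the fixed grid 2–26 Hz in 13 linear steps with
cycles $c$ log-spaced 3–12, implemented by frequency-domain
multiplication; power is the squared magnitude averaged over epochs. The
source's wavelet formula is typographically garbled, so the standard
Morlet definition is used. dB normalization divides by the mean power over
the full −2000…500 ms epoch — a baseline that includes post-event time,
unusual but implemented as specified. Half a wavelet length at each edge
is flagged unreliable per frequency, not trimmed.

## Cluster statistics

Per grid point, a dependent-samples t across subjects; points with
two-sided $p <$ `point_alpha` (default 0.01) are clustered — neighbours in
1-D, 4-connectivity in 2-D (the connectivity is a design choice; none is
published) — and each cluster's mass is its summed t. The null records the
largest absolute cluster mass per permutation; permutations are
subject-wise condition-label exchanges, equivalent to sign flips of the
paired differences; only the largest cluster enters the null, and positive
and negative families are formed separately against the common max null.
Monte-Carlo $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n_{perm}+1)$, so
the smallest attainable p is $1/(n_{perm}+1)$. Degenerate zero-variance
cells get $t = \pm\infty$ and behave as maximal. The interaction test
forms $(A_1 - A_2) - (B_1 - B_2)$ per subject and applies the one-sample
(sign-flip) variant.

Validation uses 199 permutations (smallest p 0.005, sufficient to call
clusters at the 0.01 level) rather than the 1000-permutation default, and
calibration runs use 40 synthetic subjects — the cohort size of the study
design this emulates.

## EEG preprocessing and epoching

Resample to 250 Hz (polyphase FIR), band-pass 1–100 Hz (zero-phase
Butterworth), 50 Hz notch, average reference, in that order. Channels
whose variance z-score across channels exceeds ±2 are listed for
rejection; interpolation is delegated, as is ICA. Epochs span −2000…500 ms
around switches; an epoch is rejected if any sample exceeds ±150 µV or if
the least-squares linear fit rises more than 60 µV in magnitude over the
epoch on any channel ("per epoch" is read as the fit's total rise; a
per-sample reading is exposed through the bound argument). Event filtering
removes switches < 2 s after their predecessor, same-direction
repetitions, and events whose epoch window contains another response; each
removal is attributed to the first rule that fires, so the log counts are
conserved. Event times are seconds from recording start with 0-based
sample indexing.

The session container is a single RDS file (bit-exact round trips) plus
tab-separated event export; eye-tracker samples and events are read from
delimited text. EEG from BDF/EDF is out of scope for this package's I/O —
recorded data enter as channel × sample matrices.

## A worked synthetic example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, fast_phase_rate = 0, blink_rate = 0)
ses <- synth_session(cfg)
vel <- slow_phase_velocity(lowpass_filter(interpolate_blinks(ses$okn)))
switches <- detect_switches(vel)
truth <- switch_directions(ses$schedule)
mean(sapply(truth$time,
            function(t) min(abs(switches$time - t))) <= 0.1) # recall

ei <- synth_epochs(32, "to_INT", sim_config(seed = 2), window = c(-800, 100))
map <- directed_information(ei$front, ei$back,
                            delays = seq(0, 200, 4),
                            times = seq(-600, 0, 20))
map$delays[which(map$values == max(map$values), arr.ind = TRUE)[1]]
```

## Known limitations

* The decoder's 2-D reading of the ambiguous kernel shapes is one of two
  defensible constructions; both are shipped, and accuracies on clean
  synthetic epochs are equivalent.
* Compression complexity on 25-sample windows has weak sensitivity;
  condition effects need either strong low-frequency modulation (as the
  generator default provides) or longer windows.
* The plug-in CMI bias means single-condition dir-INFO maps sit above
  zero everywhere at small epoch counts; use condition differences or
  `bias_correct = TRUE` when absolute levels matter.
* Real-data ingestion (BDF/EDF, ICA, channel interpolation) is delegated
  to dedicated EEG toolboxes; this package starts from cleaned signals.
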