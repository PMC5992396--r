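---
title: "Detecting emergency-braking intention from driver EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting emergency-braking intention from driver EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A driver who is about to brake shows neural and muscular precursors well
before the brake pedal moves: a slow negative cortical potential builds up
over motor areas in the second before the movement, and the leg musculature
activates roughly a hundred milliseconds before the pedal deflects. If those
precursors can be decoded from scalp EEG in the interval between a braking
stimulus (the lead vehicle's brake lights) and the driver's own response,
a vehicle could begin braking earlier than the driver.

`brakesense` implements a complete study of this question on simulated
driving sessions: a signal-level generator of synthetic recordings, the
preprocessing and epoching chain, time-domain feature extraction, two
classifiers (a small convolutional network and a soft-margin SVM), an
evaluation framework anchored to an exact-binomial chance level, and the
behavioural analyses of braking reaction time (BRT) and leg-muscle
activation (LEG). Because no recordings of the emulated experiment are
publicly deposited, the generator is a first-class, tested component: it
emulates the experiment's structure and signal phenomenology so that every
downstream stage can be validated end to end against known ground truth.

## The experiment the generator emulates

One participant drives four ~30 min sessions (two morning, two afternoon)
of eight blocks each; each block presents 15 emergency-braking events of a
single *experimental combination* — the presence or absence of stress (a
siren), workload (a simultaneous secondary task) and fatigue (afternoon
sessions): `C_o`, `C_s`, `C_w`, `C_s+w` in the morning, `C_f`, `C_s+f`,
`C_w+f`, `C_s+w+f` in the afternoon. Each eligible combination fills
exactly two blocks per session in pseudo-random order, giving
4 x 8 x 15 = 480 events per participant, 60 per combination. Consecutive
stimuli are separated by the 3 s brake-light interval plus a uniform
5–20 s gap.

Recorded channels:

* **EEG**, seven 10–20 electrodes (F3, F4, C3, C4, Cz, P3, P4) at 500 Hz;
* **EMG**, one channel over the right leg's tibialis anterior, 500 Hz;
* **LIGHT**, the guide vehicle's brake-light state (binary), 50 Hz;
* **BRAKE**, the participant's pedal deflection in [0, 1] at a resolution
  of 0.01, 50 Hz.

## The generative model

Reaction times are drawn per combination from truncated normal
distributions whose location, scale and truncation bounds are the published
per-condition summaries (mean, sd, min, max in ms; see `brt_model()`).
Because the published minima sit only ~1.5 scale units below the location
while the maxima sit ~3.5 above, the truncation is asymmetric and the
resulting distribution means lie 15–20 ms *above* their locations
(`tnorm_mean()` gives the closed form). This is a feature, not a bug: the
equal-weight average of the eight truncated means is ~720 ms, which is what
reconciles the per-condition table with the study-level average of
~718 ms — the printed per-condition means alone would only average 706.5.
The same framework shows a genuine limitation: the published medians
(e.g. 660 ms for `C_o` against a mean of 687) imply right-skewed data that
no truncated normal consistent with the other four summaries can reproduce;
the generator's median-based workload contrast is therefore ~6%, not the
published 7%. Both numbers are computed and reported by the test suite and
the acceptance script.

EEG background is `1/f` noise at 10 µV RMS per channel, a standard model of
resting EEG. On top of it the generator plants, per event:

* a **readiness ramp**: a linear negative drift reaching −10 µV over the
  1.2 s ending at the response, largest over the vertex
  (Cz = 1.0, C3 = 0.8, C4 = 0.6, frontal/parietal 0.2–0.3), returning to
  baseline over 300 ms. −10 µV is a mid-range literature value for
  pre-movement slow potentials at the vertex. Because the montage is later
  common-average referenced, only the topographic *contrast* of these
  weights survives (about half the nominal amplitude at Cz).
* a **visual evoked component**: a 5 µV Gaussian bump (sd 50 ms) at 200 ms
  post-stimulus, largest parietally — present so the post-stimulus epochs
  contain the expected exogenous response; it plays no role in
  classification (post-stimulus epochs are never labelled).
* 60 Hz mains interference (1 µV), removed again by the preprocessing
  filters; and an optional amplitude-outlier injector (off by default)
  that produces the gross artifacts the rejection rules exist for.

The EMG channel carries 30–90 Hz baseline muscle noise at 5 µV RMS plus one
burst per event: a band-limited noise carrier multiplied by a raised-cosine
envelope. The burst defaults need explanation, because they were
*calibrated against the package's own envelope analysis*. The LEG analysis
(below) rectifies the EMG and takes the magnitude of its analytic signal;
that magnitude has slowly decaying leading tails (the Hilbert transform of
a positive hump falls off like 1/t), so the measured
"10%-above-baseline" onset of the across-trial envelope fires *earlier*
than the planted envelope leaves zero — by an amount that grows with burst
energy. The defaults (18 µV amplitude, planted rise 745 ms → peak 855 ms,
fall 350 ms, stimulus-locked) were chosen once, during generator design, so
that the *measured* across-trial envelope reproduces the observed
phenomenology: onset ~600 ms, peak ~850 ms post-stimulus, with the burst
energetic enough that segments pass the EMG rejection rule. A
response-locked mode (`lock = "response"`) is available when burst timing
should co-vary with each trial's reaction time; it smears the across-trial
average and is not the default.

Every random quantity derives from one master seed through named sub-seeds
(`derive_seed()`), so any single stage — the schedule, one channel's noise,
one block's reaction times — can be reproduced in isolation, and identical
seeds give bit-identical sessions.

## Preprocessing

All channels are harmonized to 250 Hz: LIGHT by zero-order hold (it stays
binary), BRAKE by linear interpolation re-quantized to its 0.01 grid, and
the bio-signals by factor-2 decimation behind an order-30 linear-phase FIR
anti-alias lowpass whose group delay is explicitly compensated. The delay
compensation matters: the vehicular channels are never decimated, so an
uncompensated filter delay (~30 ms) would silently shift every EEG/EMG
sample against the event markers — we measure epochs relative to events
detected on the vehicular channels.

EEG is lowpass filtered at 45 Hz and EMG bandpassed 1–90 Hz with a
58–62 Hz mains notch, all with 2nd-order Chebyshev Type I filters
(0.5 dB passband ripple) applied forward-backward: zero phase shift at the
cost of squaring the magnitude response (an effective 4th order). Filter
type and ripple are configurable; Type I with 0.5 dB is the conventional
reading of an otherwise unspecified "Chebyshev-type" filter. EEG is then
common-average referenced: after CAR the instantaneous mean across the
seven channels is zero to machine precision.

Stimuli are the rising edges of LIGHT (threshold 0.5); the response is the
first later sample with BRAKE ≥ 0.01; BRT is their difference. Events
without a response within 2 s are flagged invalid. Each valid event yields
a data segment spanning `[stimulus, stimulus + 2 s)` — half-open, exactly
500 samples at 250 Hz, avoiding a double-counted boundary — plus 0.5 s of
pre-stimulus context used by the rejection rules.

Three automated rules replace the emulated study's visual inspection:
(a) *vehicular* — no pedal activation inside the segment; (b) *EMG* — the
post/pre-stimulus RMS ratio below a threshold (no post-stimulus muscle
activation); (c) *EEG* — any filtered sample beyond ±100 µV (gross
artifact). All thresholds are configurable. The EMG threshold defaults to
1.2: with the calibrated burst the per-segment ratio distribution sits
around 1.5–2.2 while burst-free segments concentrate at 1.0 ± 0.08, so 1.2
separates the two populations (≈2.5 sd above the burst-free mean) while
keeping ~95% of genuine segments. A stricter ratio (say 1.5) would demand
bursts so energetic that their analytic-signal tails drag the measured
envelope onset hundreds of milliseconds before 600 ms — incompatible with
the leg-movement phenomenology the generator must reproduce.

## Epochs and features

From each kept segment three 1.5 s epochs are cut: **pre-response**
(`[-1.5, 0]` s relative to the response; the braking-intention class,
+1), **post-stimulus** (`[0, 1.5]` s relative to the stimulus; used only by
the behavioural analyses, never labelled), and **non-braking** (normal
driving, −1): a window more than 3 s from every stimulus and response.
Non-braking placement is deterministic — the wider of the quiet gaps
adjacent to the event, epoch centred on its midpoint, each gap used at most
once — so datasets are exactly reproducible; events with no admissible
quiet window are skipped and their pre-response partners dropped, keeping
the classes exactly balanced.

Each epoch becomes a 7 x 10 feature map: per channel, the arithmetic means
of 10 consecutive non-overlapping 150 ms intervals. At 250 Hz an interval
is 37.5 samples, so the deterministic partition alternates 38/37 samples
(boundaries at `floor(j * 375/10 + 0.5)`). Features are linear in the
signal and tile the epoch exactly. The map flattens row-wise
(channel-major) into a 70-vector; EMG is never part of the features.

## Classifiers

**CNN.** Input 7 x 10; two convolution/pooling stages (50 then 100 kernels
of 4 x 4, ReLU, non-overlapping 2 x 2 max pooling); dense hidden layer of
100 sigmoid units; 2-unit soft-max output. Convolutions use SAME zero
padding and pooling rounds fractional sizes up — the unique standard
convention under which the stage outputs are 50 maps of 4 x 5 and 100 maps
of 2 x 3 (600 dense inputs), the published dimensions; `layer_shapes()`
computes the arithmetic and the tests assert the forward pass realises it.
Under this topology the parameter counts are 850 (stage 1), 80,100
(stage 2) and 60,302 (dense layers); the per-layer parameter counts
reported for this architecture are mutually inconsistent and are not used as targets.
Training follows the stated protocol: 200 stochastic-gradient steps on the
soft-max cross-entropy at learning rate 0.005, each step drawing a fresh
batch of 20% of the training data, with the remainder scored per step when
the history is requested. Two implementation choices depart from a literal
reading and are deliberate:

* *Dropout.* The source description gives a "15% retention rate" on the
  convolution stages and "85% retention" on the dense layer. Keeping only
  15% of conv activations stalls learning completely at this network's
  scale (training accuracy stays at chance even on its own training data),
  which is irreconcilable with the reported accuracies; read as a 15%
  *drop* rate it matches the dense layer's 85% retention. The default is
  therefore retention 0.85 everywhere (inverted dropout, training only);
  the literal 0.15 remains available in `cnn_config()`.
* *Input standardisation.* Features are z-scored inside `train_cnn()`
  (training statistics stored in the model, re-applied at prediction).
  Raw microvolt magnitudes saturate the sigmoid layer and plain SGD at
  0.005 cannot recover.

The numerical core (im2col convolution, pooling with argmax bookkeeping,
backpropagation, a self-contained xorshift generator for batches and
dropout masks) is compiled C++; training is bit-reproducible for a given
seed and platform.

**SVM.** The usual soft-margin problem — minimise
`C * sum(xi) + ||w||^2 / 2` subject to
`y_i (w' phi(x_i) + b) >= 1 - xi_i` — with an RBF kernel and
inverse-variance bandwidth by default, solved exactly by the libsvm dual
solver (via `e1071`); scores are signed distances oriented so positive
means braking intention. Because it is left open
whether the SVM shared the CNN's batched 200-step procedure, a linear
hinge-loss subgradient route with the same step/batch schedule is also
provided (`method = "sgd"`); the exact solver is the default.

## Evaluation

Accuracy is `100 * (TP + TN) / (TP + TN + FP + FN)`. The evaluation
protocol is repeated holdout: 75% training / 25% evaluation, redrawn
independently each repetition (100 by default), stratified by class so both
classes appear in every evaluation set (the stratification is the one
addition to the stated protocol; it removes the possibility of a
single-class evaluation set on small data). Reported per run: the accuracy
distribution (mean, sd, min, max), per-repetition AUC, and an ROC and
precision-recall curve over the pooled evaluation scores (pooling is our
convention; per-repetition AUCs are also kept).

The significance anchor is the exact-binomial chance level: the smallest
accuracy `100 * k / n` whose binomial CDF at `p = 1/2` reaches
`1 - alpha`. For two classes, 600 samples and alpha 0.05 this is 53.33%;
the reported value (53.6%) differs by a
rounding/convention gap of under half a point, and the exact computation is
treated as authoritative. Accuracy distributions are compared against the
threshold with the Wilcoxon signed-rank test, between classifiers with the
rank-sum test, and across three or more groups with Kruskal–Wallis, all
two-sided.

Three study-level protocols mirror the emulated study's analyses: per-participant
repeated holdout; pooled (all participants concatenated); and
leave-one-participant-out, where the classifier trains on everyone else
(repetitions re-seed the training randomness — for the deterministic SVM
solver the repetitions coincide, which is reported as zero spread) and is
evaluated on the entire held-out participant. The chance level attached to
a protocol uses the smallest dataset size across participants, following
the emulated study's convention.

## Behavioural analyses

`brt_summary()` reproduces the reaction-time table (n, mean, sd, min, max,
median per combination), the Kruskal–Wallis omnibus across combinations,
rank-sum contrasts of every factor-bearing combination against the
factor-free baseline `C_o`, and the percent change of medians against
baseline.

`leg_envelope()` computes the leg-movement signal: per stimulus-locked
trial, high-pass at 10 Hz (2nd-order Chebyshev, zero-phase), rectify, take
the magnitude of the analytic signal (FFT construction); average across
trials; smooth with a 50 ms moving average. The onset is the first time the
average envelope exceeds its pre-stimulus baseline (measured
−200…+100 ms around the stimulus) by 10% *and stays above for at least
100 ms* — the sustained-crossing requirement suppresses spurious
threshold crossings by noise excursions; the peak is the maximum. The
first and last 100 ms of the window are excluded from both searches
(analytic-signal edge artifacts). For a pure sinusoid of amplitude A this
chain converges to the rectified mean 2A/π, the closed form the tests
check.

## What the synthetic data do and do not show

The generator reproduces the experiment's structure (design arithmetic,
multi-rate channels, quantization), its behavioural statistics (truncated
reaction-time distributions, the workload effect), and the phenomenology of
its bio-signals (1/f EEG with a vertex-weighted readiness ramp, a
parietal evoked response, a leg burst with the observed envelope
latencies). It does not attempt realistic artifact taxonomies (blinks,
chewing), volume-conduction-correct topographies, non-stationary noise, or
inter-participant variability beyond independent noise realisations —
participants differ only by seed. Consequently, passing the
classification checks demonstrates that the pipeline is correct and
sensitive (it finds planted signal and is calibrated on null data); it
does not demonstrate that real drivers' braking intention is decodable at
any particular accuracy. The published human accuracies (~71% mean) are
not reproduction targets, because the underlying recordings are not
available.

## Problem sizes used by the tests

The automated checks run on deliberately scaled-down worlds chosen as the
smallest sizes at which each property is statistically stable: single-session
participants with 2 blocks (null-calibration worlds: type-I behaviour does
not depend on n), 6 blocks (signal-detection worlds: large enough that both
classifiers clear the chance threshold with a ~10-point margin), 20
evaluation repetitions instead of 100, and a 7-participant
morning+afternoon cohort (1,680 events) for the reaction-time and envelope
recovery checks. The acceptance script uses the same sizes and recomputes
everything from scratch at run time.

## Known limitations

* The truncated-normal family cannot reproduce the published medians
  together with the published means/sds/ranges (see above); median-based
  contrasts on synthetic data land near 6%, not 7%.
* The leg-envelope onset is a threshold crossing on a shallow slope; its
  across-seed spread is ~±20 ms even with hundreds of trials, and the
  measured onset is tied to the calibrated burst defaults. Changing burst
  amplitude or width shifts the measured onset away from 600 ms.
* Leave-one-out with the deterministic SVM solver has degenerate
  repetitions (identical accuracy every time); the signed-rank test
  against chance is then uninformative and reported as NA-like p-values.
* The CNN is trained with plain SGD; no early stopping, no optimiser
  schedule. At very small n (a handful of training batches of fewer than
  ten instances) it can fail to beat chance even on separable data.
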