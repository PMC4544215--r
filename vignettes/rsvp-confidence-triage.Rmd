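---
title: "Confidence-gated single-trial classification for RSVP target detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-gated single-trial classification for RSVP target detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsvpTriage)
```

## The problem

In a rapid serial visual presentation (RSVP) triage system, an analyst
watches images stream past at 2 Hz while a classifier reads their EEG and
flags images whose neural response looks like a target detection. The
canonical signature is the P3: a large, slow positive deflection over
midline-parietal scalp, peaking several hundred milliseconds after a rare,
task-relevant stimulus. Real image streams, however, also contain rare
stimuli that *look like* targets but are not (a person without a weapon
among target people with weapons). These non-targets evoke P3-like
responses of intermediate size, and a classifier trained to detect rare
evoked responses confuses them with targets far more often than it confuses
the frequent background images.

This package implements the full analysis chain for studying that problem
and one mitigation for it: score every trial, convert the score's distance
from the decision threshold into a confidence value, and route
low-confidence trials to a secondary labeler (simulated here as a perfectly
accurate manual annotator), trading labeling time for accuracy.

Because raw EEG from such experiments is not publicly deposited, the
package is built around a synthetic-session generator that reproduces the
statistical structure the analysis assumes. Every downstream stage is
exercised end-to-end on generated sessions; the generator is itself
first-class, tested code.

## The synthetic session generator

`simulationConfig()` fixes the study conditions:

* **Sequence layout.** Six blocks per session at 2 Hz. Target-Only (TO)
  condition: 120 s blocks, target:background ratio 1:20, hence
  `floor(240 / 21) = 11` targets among 240 stimuli per block. Target plus
  Non-target (TN) condition: 134 s blocks with 1:14 target and 1:14
  non-target ratios, hence 16 of each among 268 stimuli. Rare stimuli are
  never adjacent and every rare stimulus is followed by at least two
  backgrounds (the attentional-blink guard).
* **Rare-slot sampling.** Admissible rare-position sets (pairwise gaps of
  at least `gap + 1`, last position at least `gap` from the block end) are
  in bijection with unconstrained k-subsets via
  `p_i -> p_i - (i - 1) * gap`, so sampling the unconstrained subset and
  mapping back is *exactly* uniform over admissible sets. We chose this
  over sequential rejection with look-ahead because uniformity holds by
  construction and is verified by enumeration in the test suite.
* **Evoked response.** A raised-cosine bump peaking at 550 ms with 250 ms
  half width (support 300–800 ms), projected through a fixed smooth
  spatial pattern maximal at the Pz-role channel. Class amplitudes are
  parameterized as the *mean* amplitude over the 400–800 ms analysis
  window at Pz — the quantity windowed P3 analyses report — with defaults
  13.66 µV (target), −0.44 µV (background) and their midpoint 6.61 µV for
  non-targets, which are described qualitatively as intermediate. Because
  the template support lies inside (0, 800] ms and stimuli are 500 ms
  apart, neighboring responses never overlap a stimulus's own 400–800 ms
  window, so a noise-free session reproduces the configured amplitudes to
  machine precision.
* **Noise.** Independent 1/f ("pink") Gaussian noise per channel, 20 µV
  standard deviation by default. This value calibrates the pipeline into
  the regime the experimental literature reports for this paradigm:
  target-vs-background Az near 0.99 in the TO condition, with TN
  non-target misclassification around 30–40%. White noise is available as
  an option.
* **Behavior.** Each stimulus elicits a button press with class-dependent
  probability (defaults 0.95 / 0.05 / 0.002 for target / non-target /
  background). Reaction times are log-normal — positive support, right
  skew — parameterized by the median (514.67 ms TO, 602.82 ms TN) with
  log-sd 0.25, so the configured medians are population medians and are
  recovered from large simulated samples.

A single integer seed fully determines the sequence, the EEG and the
presses.

### What the generator does *not* emulate

Spatially correlated noise, eye/muscle artifacts, amplitude attenuation
from attentional lapses, latency jitter of the evoked response, and any
dependence of behavior on the neural response (simulated presses and EEG
are conditionally independent given the stimulus class). One consequence
shows up in the confidence analyses: real non-targets produce occasional
full-blown target-like responses that are misclassified *with high
confidence*, so their misclassification rate stays high at every
confidence threshold. Our unimodal non-target amplitude model instead
drains non-targets out of the high-confidence subset as the threshold
rises. Tests of the confidence profile therefore assert the shape over the
thresholds at which non-targets are still retained, and passing them says
nothing about high-confidence errors in real recordings.

## Preprocessing

The classification stream is band-passed 1–10.66 Hz (order-4 Butterworth,
zero-phase by default so evoked latencies are preserved; a causal flag
exists), decimated to 32 Hz (integer decimation is exact here because the
band-pass has already removed energy above the new Nyquist), and epoched
`[0, 1000)` ms — exactly 32 samples per trial under the half-open sample
convention with the onset at sample `ceil(start * rate / 1000)`. The ERP
stream instead epochs `[−500, 1000)` ms at the acquisition rate and
subtracts the `[−500, 0)` ms per-channel baseline. Trials whose window
leaves the recording are dropped and logged, never padded, since padding
biases averages.

## The behavioral model

A press within (200, 1000] ms of a rare stimulus is attributed to it; a
press eligible for two rare stimuli (impossible under the 2-background gap
at 2 Hz, possible for arbitrary input) goes to the most recent one, the
reaction-time-plausible choice. Each press is used at most once, each
stimulus absorbs at most one press, and unattributed presses are
background false positives. Hit rate and false-positive rate follow the
standard ratios with half-count (1/(2N)) edge correction for degenerate
proportions, and sensitivity is the probit difference
`d' = Z(HR) − Z(FPR)`. The pooled false-positive rate uses both non-rare
classes by default; per-class rates are reported alongside since either
pooling convention is defensible.

## xDAWN spatial filtering

The recorded matrix X (samples × channels) is modeled as
`X = D1 A1 + D2 A2 + H` with 0/1 Toeplitz designs D1 (target onsets) and
D2 (all onsets). The evoked prototypes are estimated jointly by least
squares, and filters u maximize the signal to signal-plus-noise ratio

SSNR(u) = (uᵀ Â1ᵀ D1ᵀ D1 Â1 u) / (uᵀ Xᵀ X u),

solved as a generalized symmetric eigenproblem by Cholesky whitening of
Xᵀ X. Numerical choices: Xᵀ X receives a trace-scaled ridge
(`lambda = 1e-9`) before factorization; filters are normalized to unit
norm in that metric so filtered time courses are comparable across
filters; reported SSNR values are Rayleigh quotients at the raw Xᵀ X,
sorted descending; a rank-deficient `[D1; D2]` falls back to the
Moore–Penrose pseudoinverse with a warning (short synthetic blocks can
produce collinear designs). The response lengths are N1 = N2 = one epoch
(32 samples), the natural choice matching the feature dimensions.

Inside the cross-validated pipeline the training X is assembled by
stacking the training-fold epochs in time order, with every epoch start an
onset. Folds are trial slices, so this keeps train/validation separation
exact at the cost of duplicating the 500 ms overlap between adjacent 1 s
epochs; the algebra above is indifferent to the duplication, and the
module also accepts genuinely continuous X via `buildDesign()` directly.

Features are the 8 filtered time courses concatenated filter-major:
8 × 32 = 256 values per trial.

## Bayesian linear discriminant analysis

BLDA is Bayesian linear regression onto class-balanced targets (+N/N1 for
targets, −N/N0 for the rest — the coding that absorbs the 1:20 class
imbalance), with an isotropic Gaussian prior of precision alpha over the
augmented weight vector and noise precision beta. Alpha and beta maximize
the marginal likelihood via the classical fixed-point updates (effective
degrees of freedom for alpha, residual variance for beta), iterated to
`|Δ log alpha| + |Δ log beta| < 1e-6` or 100 iterations; one SVD of the
design is reused across iterations, so the fit is fast at these problem
sizes. With frozen hyperparameters the posterior mean reduces to ridge
regression with penalty alpha/beta, which the tests exploit as a
closed-form oracle. No feature standardization is applied by default: the
xDAWN normalization already equalizes filter scales.

Note that under unbalanced class sizes the zero crossing of the score is
*not* the decision boundary; the boundary is always the explicitly
selected threshold below.

## Threshold, confidence, and the sweep

The discrimination threshold κ maximizes Youden's J = TPR − FPR over all
midpoints between adjacent distinct scores, ties broken toward the higher
cut (fewer predicted targets — the conservative choice for triage).
Nested cross-validation provides a dedicated 10% slice for establishing κ;
that is the default, with a switch to derive κ from the training scores
instead, since descriptions of this design vary on the point. If the
threshold slice happens to contain a single class (possible in very small
sessions), the pipeline falls back to the training scores with a message.

Confidence is the score's normalized distance from κ:
`(score − κ)/(max − κ)` above the threshold and `(score − κ)/(min − κ)`
below, with the extrema taken from the training set, clipped to [0, 1] for
validation scores that fall outside the training range. It is invariant to
affine transformations of the score axis and monotone in |score − κ| on
each side.

Confidence-percentile thresholds use the strict-below empirical quantile:
the threshold for p% is the `floor(p/100 · n) + 1`-th order statistic, so
0% retains everything and boundary ties stay in the retained
(high-confidence) subset.

## Evaluation and mitigation

Folds are contiguous 10% slices of the time-ordered trials (sizes differ
by at most one; the first `n mod 10` slices take the extra trial). For
fold k: validation = slice k, threshold = slice k+1 (circularly), training
= the remaining eight slices; the rotation itself is a free choice since
only the 80/10/10 proportions and contiguity are fixed. Az is the
trapezoidal ROC area computed as the Mann–Whitney probability with ties
counted half, pooled over validation scores across folds (per-fold values
are also reported). Misclassification is directional: targets predicted
non-target; non-targets/backgrounds predicted target.

The mitigation simulation gives every trial below the confidence threshold
its true label (a perfectly accurate manual annotator) and recomputes
metrics over *all* trials; relabeled trials enter the Az computation as
maximal-certainty scores (beyond the observed extrema) so they cannot
perturb the ordering of retained trials. Relabeling can only fix errors,
so mitigated misclassification is pointwise dominated by classifier-only
misclassification — asserted per class at every threshold in the tests.
The labeling-time cost is linear: manually labeling a fraction f at 1 s
per image, against 0.5 s per RSVP image, adds `100 · f · 1 / 0.5` percent
to total labeling time — 60% at f = 0.30.

## Problem sizes used in the checks

The end-to-end checks run five full TO sessions (six blocks, 1440 trials
each) through the complete chain, two-block sessions for the null
(no-signal) and amplitude-recovery simulations, and one full TN session
for the misclassification profile; oracle equivalences (pair-counting Az,
cut-point enumeration, 2×2 generalized eigenproblem by hand, 10^5 random
filters against the top SSNR, ridge closed form) run on small randomized
instances. These sizes make the whole suite complete in about a minute on
one core while leaving Monte-Carlo margins that the assertions state
explicitly.

## Known limitations

* The generator's independence assumptions (noise across channels,
  behavior given stimulus class) are idealizations; see above for what
  that implies about confidence-profile conclusions.
* Confidence is a pure distance-to-boundary measure; density-based or
  multi-source confidence estimates are out of scope.
* Group-level inferential statistics (signed-rank tests, ANOVA,
  multiple-comparison correction across subjects) are not reimplemented;
  standard R facilities apply directly to the per-session tables this
  package emits.
* Continuous data are exchanged as tab-delimited text with a JSON
  metadata sidecar; EDF/BDF import/export is not provided.

## A worked session

```{r example, eval = FALSE}
cfg <- simulationConfig("TN", seed = 1)
session <- simulateSession(cfg)

behavioralSummary(session$events)

epochs <- preprocessForClassification(session$eeg, session$events)
report <- runPipeline(epochs, "tn_tvbnt")
report
sweepConfidence(report)
```
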