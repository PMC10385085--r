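---
title: "Heart-rate affect recognition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate affect recognition: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affecthr)
```

## The problem

Children on the autism spectrum often cannot report their emotional state,
and facial analysis alone is unreliable in uncontrolled settings (head pose,
occlusion, lighting). Heart rate, captured continuously by a smartwatch, is a
robust alternative carrier of affective information: arousal-linked states
such as anger or fear raise it, calm engagement lowers it. `affecthr`
implements the full analysis chain for three-class affect recognition
(negative / positive / neutral) from a beats-per-minute (BPM) stream:

1. **Semi-automated annotation.** A frame-level facial-expression
   recognition (FER) stream — eight fine classes with a confidence in
   [0, 1] — labels the time-aligned heart-rate stream in fixed windows, with
   low-confidence windows escalated to a human annotator.
2. **Feature extraction.** Each window of $n$ consecutive BPM samples
   $V = (h(t-(n-1)), \ldots, h(t))$ is used either raw or as its orthonormal
   Haar discrete-wavelet-transform (DWT) sub-band coefficients.
3. **Classification.** SVM, $k$-NN and random forest under stratified
   ten-fold cross-validation, in a subject-dependent (intra-subject) and a
   subject-independent (inter-subject) protocol.

Because the kind of video/HR cohort this method targets cannot be shared,
the package ships a synthetic cohort generator with the same statistical
skeleton, and every claim the test suite makes is made on that generator.

## The synthetic cohort generator

A latent per-second affect process drives both observable streams. It is
semi-Markov: episode states are drawn i.i.d. from `state_probs` and episode
lengths are $1 + \mathrm{Geom}(1/\bar{d})$ seconds with mean dwell
$\bar{d}$ = `dwell_mean_s` (default 30 s). This is the simplest process that
produces contiguous emotional episodes — a child is happy for a stretch after
a success, frustrated for a stretch after a failure — while keeping every
moment's ground truth available to the tests.

The heart-rate stream is
$\mathrm{bpm}_k = b + \delta(s_k) + \varepsilon_k$, clipped to the
physiological range [30, 220]: a per-subject baseline
$b \sim \mathcal{N}(96, 8^2)$ BPM, a state offset $\delta$ (defaults
+12 BPM negative, −6 BPM positive, 0 neutral), and Gaussian sensor noise
(sd 2 BPM). With the default episode mix (0.3 / 0.3 / 0.4) the cohort grand
mean sits near 97–98 BPM, matching the ~96.8 BPM average such cohorts show;
nine subjects with session durations uniform on 480–846 s reproduce the
field's session-length envelope. The generator is calibrated to exactly
these summary statistics (mean, extremes, durations) because that is all
that is typically reported for such cohorts; it makes no claim about
autocorrelation or heart-rate-variability structure beyond the latent
process itself.

The FER stream emits one prediction per frame (25 fps). With probability
`fer_accuracy` (default 0.8) the fine label is drawn from the cluster
consistent with the true state — negative → {fear, anger, sadness, disgust},
positive → {happiness}, neutral → {neutral} — otherwise from the remaining
labels. Surprise and contempt appear only as recognizer noise: the
three-class clustering rule assigns them to no cluster, so no latent state
emits them. Confidences are Beta(8, 2) for consistent frames and Beta(2, 4)
otherwise; the separation matters, because confidence-based escalation is
only meaningful when confidence correlates with correctness.

**What the generator does not emulate:** PPG waveforms, inter-beat
intervals, motion artifacts, sensor dropout, and any within-state heart-rate
dynamics (trends, habituation). Passing tests therefore demonstrate that the
*pipeline machinery* is correct and that the *protocol-level findings*
(intra vs. inter, feature schemes) behave as expected when the assumed
signal structure is present — not that a particular accuracy will be reached
on any real cohort.

## Annotation

Videos are cut into clips of $n_f = \mathrm{fps} \times w$ frames (50 at
25 fps and $w = 2$ s); a trailing remainder is discarded so all windows have
equal length. Each clip is summarized by a **representative frame** chosen by
two criteria: its label must be the clip's most frequent label, and among
frames with that label it must have maximal confidence. We implement this as
a single lexicographic maximum over frames — (label frequency, confidence,
lowest frame index) — which realizes both criteria and makes every tie
deterministic and order-stable. The test suite checks this choice against an
independent brute-force scan on ten thousand random clips, including
constructed exact-frequency ties.

If the representative confidence falls **strictly below** the threshold
(default 0.5, configurable; the boundary value stays automatic) the clip is
escalated to a human annotator, modeled as a callable interface; in tests it
is backed by the ground-truth state sequence (modal state over the clip's
span). Otherwise the fine label is mapped to its affect cluster. The
surprise → positive and contempt → negative defaults are explicit choices on
a point the clustering rule leaves open, and both are configurable.

One practical note: because the representative frame maximizes confidence
over dozens of frames, its confidence is typically high (the maximum of ~50
Beta(8, 2)-ish draws), so at the default threshold of 0.5 very few clips
escalate. Escalation rates become substantial only at thresholds near 1 —
the monotone sweep from 0 % at threshold 0 to 100 % at threshold 1 is part
of the acceptance suite.

Since the two streams share a clock, heart-rate window $k$ (samples
$[kn, (k+1)n)$, $n = w \times$ sampling rate) receives clip $k$'s label; the
shorter stream limits the labeled-window count, and an `offset_s`
configuration shifts the heart-rate indexing when starts differ.

## Haar DWT features

The analysis step is the orthonormal Haar filter bank,
$a_i = (s_{2i} + s_{2i+1})/\sqrt{2}$, $d_i = (s_{2i} - s_{2i+1})/\sqrt{2}$,
applied recursively to the approximation band (sub-band coding); the feature
vector concatenates $[A_L, D_L, \ldots, D_1]$. Choices that were genuinely
open, and how we fixed them:

- **Normalization.** The $1/\sqrt{2}$ (orthonormal) convention rather than
  pairwise averaging: it makes Parseval energy conservation
  $\|A_L\|^2 + \sum_k \|D_k\|^2 = \|s\|^2$ an exactly testable invariant and
  the inverse transform the transpose. Tests assert energy conservation and
  perfect reconstruction at $10^{-9}$ and coefficient-level agreement with
  PyWavelets (orthonormal Haar, periodization mode) at $10^{-10}$.
- **Depth.** Defaults to the maximal $L = \lfloor \log_2 n \rfloor$; at the
  2 s / 1 Hz default, $n = 2$ and $L = 1$.
- **Coefficients, not statistics.** At these tiny $n$ the concatenated
  coefficients preserve all information and have deterministic length $n$
  (critical sampling); per-band energy/mean/sd summaries are available via
  `band_stats = TRUE` for longer windows.
- **Odd lengths.** $n$ is configuration-dependent (3 s or 5 s windows at
  1 Hz give odd $n$), so odd bands repeat their last sample before the step;
  a strict mode errors instead. Padding necessarily breaks exact energy
  conservation and the length-$n$ property, so those invariants are asserted
  for dyadic $n$.
- **No detrending.** Heart-rate windows enter the transform as-is;
  standardization happens later, per training fold.

## Evaluation

Intra-subject datasets contain one subject each (train and test within an
individual); the inter-subject dataset pools everyone. Cross-validation is
stratified ten-fold — within each class, shuffled windows are dealt
round-robin with the dealing position carried across classes, so fold sizes
differ by at most one and each fold mirrors the class balance. Features are
z-scored with training-fold statistics only. Classifiers use standard
defaults (RBF SVM, cost 1; 5-NN Euclidean; 100-tree random forest, Gini)
since no hyperparameters are mandated by the protocol. Multiclass accuracy
is the confusion-matrix trace over its total — the only consistent
three-class reading of the binary $(TP+TN)/(TP+TN+FP+FN)$ definition — and
macro precision/recall (zero for never-predicted classes, logged via the
confusion matrix itself) combine into the F1 as their harmonic mean.

Temporal autocorrelation is a real caveat: adjacent windows are dependent,
so random folds are optimistic for within-subject generalization claims. We
keep random stratified folds as the default because that matches the
standard protocol; a temporally blocked alternative would be the natural
extension.

## Problem sizes and expectations in the test suite

The suite runs the full nine-subject default cohort (≈3,000 two-second
windows) for the calibration, recovery and ordering checks, and scales
Monte-Carlo checks to where their statistics are sharp: state-frequency
convergence uses 20,000 s at 5 s dwell (≈4,000 independent episodes, so the
±0.02 band is ~3 standard errors), the permutation null uses 3,000 balanced
windows against a 99 % binomial band around 1/3, and cohort-level
calibration checks average over five seeds because a single nine-subject
cohort carries ~2.7 BPM of baseline sampling noise in its grand mean. With
clearly separated state offsets and no baseline variation the inter-subject
SVM recovers the latent states at well above 0.8 accuracy; with the default
8 BPM baseline spread, inter-subject accuracy drops far below intra-subject
accuracy — the qualitative signature of subject-independent heart-rate
recognition — while the DWT features track the raw-signal features closely
(they are an orthogonal transform of the same window, so large gaps in
either direction would be suspicious at $n = 2$).

## Known limitations

- The generator's affect process has no within-episode dynamics and no
  subject-specific reactivity differences; real effect sizes will be smaller
  and less stationary.
- Escalation behavior at the default threshold is degenerate (≈0 %) because
  representative confidences are maxima; studying annotator burden requires
  sweeping the threshold.
- The pipeline is BPM-only by design: no HRV, no frequency-domain features,
  no wavelets beyond Haar.
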