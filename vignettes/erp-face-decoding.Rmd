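---
title: "Decoding face identity and expression from ERP topographies: models, inference, and the synthetic ground truth"
author: "erpdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding face identity and expression from ERP topographies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdecode)
```

## The analysis in one paragraph

A participant views one of 16 face images (4 identities crossed with 4
emotional expressions), remembers both dimensions across a delay, and is
occasionally tested on one of them. The EEG is epoched around stimulus
onset (-500 to +1496 ms at 250 Hz, 59 scalp channels, 640 analysis trials
per participant). At every 4-ms time point, the spatial pattern of voltage
across channels — the scalp topography — serves as a feature vector from
which a multiclass classifier tries to read out *which* identity (or
expression) is being perceived or held in memory. The accuracy of that
readout, traced over time and tested at the group level with a
cluster-based permutation procedure, is the scientific result: identity
information is strong early and fades through the delay, expression
information rises more slowly but is sustained, and the previous trial's
identity can re-emerge when the next stimulus appears.

`erpdecode` implements that pipeline end to end, together with a synthetic
epoch generator whose ground truth is known exactly, so that every stage —
bookkeeping, preprocessing, decoding, and inference — is testable without
any recorded data.

## The decoder

**Averaged-fold cross-validation.** For each class, trials are randomly
split into 3 equal groups (`partitionBalanced()`; 160 trials per class
give 3 × 53 with one random trial dropped) and each group's trials are
averaged into one scalp vector per class per time point. Averaging ~53
trials boosts the signal-to-noise ratio of the feature vectors at the cost
of leaving only 3 exemplars per class; classifiers train on 2 groups'
averages and predict the held-out group's, rotating over all 3, and the
whole procedure is repeated with 10 fresh random assignments. Accuracy at
a time point is the mean over 4 classes × 3 folds × 10 iterations = 120
attempts.

**ECOC one-vs-rest linear SVMs.** The 4-class problem is reduced to 4
binary soft-margin linear SVMs (one class against the rest). The binary
learners are trained on features standardized by the training rows'
per-channel mean and standard deviation; the analysis this package
implements fixes the classifier family but not its hyperparameters, so
the package pins the field's reference defaults: cost C = 1, unweighted classes, and
prediction by minimizing the average binary hinge loss over the
one-vs-rest coding matrix, with exact ties resolved to the lowest class
code so that every prediction is deterministic. The dual problem is solved
by a small deterministic SMO solver (maximal-violating-pair selection,
tolerance 1e-6); the test suite verifies its decision values against an
independent SVM implementation on randomized problems.

**Fold assignment policy.** One fold assignment is drawn per iteration and
used at every time point of that iteration, so time courses are comparable
across time; all randomness descends from one master seed through a fixed
splitting rule, making every result bit-reproducible.

**Variants.** `decodeCrosstime()` averages the epoch into 100-ms windows
(20 over the full epoch) and trains on each window while testing on all of
them; a diagonal-dominant matrix indicates a dynamically evolving code.
`decodeCrossdim()` trains on 3 levels of the task-irrelevant dimension and
tests on the held-out level (4 rotations, within-class averages per level,
no subsampling iterations — train/test membership is fully determined), so
that no stimulus image is shared between training and testing.
`relabelPreviousTrial()` re-labels every trial with its predecessor's
identity or expression (dropping the session's first trial) for
reactivation analyses.

## Signal conditioning

* **Low-pass filter** (`lowpassFilter()`): zero-phase two-pass FIR,
  Hamming-windowed sinc of order ≈ 3·fs/cutoff, kernel normalized to exact
  unit DC gain, applied per epoch via anti-symmetric reflection padding.
  The default 6 Hz cutoff excludes alpha-band (8-12 Hz) activity from the
  features. Any zero-phase FIR meeting the DC/attenuation contract would
  do — the analysis depends on phase-locked low-frequency content, not on
  a specific kernel.
* **Baseline correction** (`baselineCorrect()`): per trial and channel,
  the mean over [-500, 0) ms is subtracted. The source description leaves
  the baseline procedure implicit; the package applies it before decoding
  by default and exposes it as a config flag (`baselineWindow`) so its
  effect is testable.
* **Accuracy smoothing** (`smoothSeries()`): 5-point centered moving
  average (±8 ms at 250 Hz) applied to accuracy series only, never to the
  EEG. At the series edges the window shrinks symmetrically rather than
  zero-padding, which would bias edge accuracies toward 0 and could
  manufacture spurious clusters.

## Group-level inference

Post-onset time points are tested against chance (1/4) with one-sample
one-tailed t tests (the decoder cannot be meaningfully below chance);
contiguous runs of points with p < 0.05 form clusters whose summed t is
the cluster mass. The null distribution of the *largest* mass is built by
relabeling stored test predictions — no retraining: per permutation and
participant, one uniformly drawn permutation of the 4 class codes is
applied to the true labels *identically at every time point*, which keeps
the temporal autocorrelation of the accuracy series intact; the relabeled
series is smoothed with the same 5-point rule and clustered with the same
threshold. Relabeling is implemented as a permutation of the class codes
(rather than a shuffle of the label vector) because a code permutation is
constant across time points by construction and preserves class balance. Cluster p-values use
the counting estimator p = #(null ≥ mass)/n~perm~, floored at 1/n~perm~
(1000 permutations give a 10^-3^ resolution; floored values render as
p < 0.001 in reports); percentile-interpolation alternatives exist, but
the counting estimator is the standard, conservative choice. Condition differences (identity vs expression) use
paired two-tailed t tests with clusters formed separately for positive and
negative exceedances and a null built by swapping each participant's two
(already smoothed) series with probability 1/2; observed |mass| is
compared against the null of largest |mass|.

Zero-variance columns (e.g., both conditions saturated at accuracy 1.0)
yield t = ±Inf with the sign of the mean difference, and exactly 0 when
the mean equals the null value; this is documented behavior, not an error,
and infinite masses propagate consistently through the permutation
machinery.

The behavioral comparison is a paired t test plus the JZS Bayes factor:
a Cauchy(0, r = 0.707) prior on the standardized effect size, with the
marginal likelihood under the alternative computed by adaptive quadrature
of the noncentral-t density against the prior. The unit tests check it
against an independent quadrature route (the Zellner–Siow inverse-gamma
g-integral).

## The synthetic generator: what it emulates, and what it does not

`simulateParticipant()` builds each trial as

signal(t) = g~ID~ · e~ID~(t) · T~ID~(identity, s(t)) +
g~EX~ · e~EX~(t) · T~EX~(expression, s(t)) +
ρ · e~R~(t) · T~ID~(previous identity, s(t)) + noise(t)

* **Topographies** T: one unit-norm random channel vector per class, per
  dimension, per *pattern segment*. Segments (defaults [0,200), [200,500),
  [500,1500) ms) let the coding pattern change over time, which is what
  produces a diagonal-dominant temporal generalization matrix; consecutive
  segments are positively but imperfectly correlated.
* **Envelopes** e(·) in [0,1]: zero before onset, squared quarter-sine
  rise to 1 at the peak, then a half-cosine fall over a finite decay
  duration that lands *exactly* on the plateau (0 for identity, 0.5 for
  expression by default). A finite-duration fall rather than an
  exponential tail makes "the plateau is reached" an exact statement that
  tests can assert to 1e-9, and gives the identity envelope a definite
  end. The reactivation envelope is a raised-cosine bump confined to
  [80, 480] ms post-onset, modeling re-emergence of the previous trial's
  identity pattern (identity only, modeling identity-specific reactivation; the
  expression reactivation gain simply stays 0 and both are configurable
  for falsification).
* **Noise**: Gaussian AR(1) in time (default φ = 0.3 within signal
  studies, 0.5 in the null suites; innovation sd 10 µV), independent
  across channels and trials, plus one alpha-band sinusoid per trial
  (frequency uniform in 8-12 Hz, uniform phase, common to all channels).
  AR(1) rather than 1/f noise is a deliberate choice: it gives the one
  autocorrelation knob that the family-wise-error test needs to exercise
  the permutation scheme's central claim. Channel-wise spatial correlation
  is not modeled — neither the decoder nor the statistics require it.
* **Labels**: balanced over the 16 identity × expression cells and
  sequenced so that consecutive trials never repeat either dimension, as
  in the task; an optional 80 extra flagged trials reproduce the 720-trial
  session from which post-test trials are excluded. Block breaks are not
  modeled: only the first trial and post-test trials are ever excluded, so
  previous-trial relabeling runs straight through the session.
* **Behavior**: per-participant true accuracies drawn around 0.70 and
  reported as binomial draws over 40 test trials per dimension — a purely
  synthetic stand-in for the unavailable behavioral reports.

**Default amplitudes are chosen for clean parameter recovery, not to
match the modest effect sizes typical of real recordings.** With the defaults (identity gain
12 µV, fast rise at 60-160 ms, decay ending ~720 ms; expression gain
4 µV, slower rise, sustained plateau 2 µV; noise sd 10 µV), both decoding
curves saturate through mid-perception, identity's accuracy collapse
begins just after 500 ms, and the expression plateau keeps its curve high
through the delay. That construction confines identity > expression
clusters to the perception period and expression > identity clusters to
the delay — the qualitative crossover the recovery suite asserts — without
the wrong-direction boundary clusters that slow envelope crossings would
produce under the ±250 ms smear of the 6-Hz filter. Real ERP class
differences are an order of magnitude smaller; passing recovery tests
shows the pipeline recovers structure that is present, not that real data
would yield these accuracies.

Two phenomena of the averaged-fold design are worth knowing about, because
the generator exposes them and real data contain them too:

* **Design leakage into previous-trial decoding.** Because consecutive
  trials never repeat a dimension, trials labeled "previous identity = c"
  systematically under-represent current-identity c, so the *current*
  trial's identity signal leaks an anti-pattern of magnitude ≈ gain/3 into
  previous-trial group means. The reactivation recovery condition
  therefore uses small current-trial gains (0.5/0.4 µV, well below the
  fold-level noise) with a 2 µV reactivation bump, so that a significant
  previous-trial cluster can only come from the injected reactivation —
  and the ρ = 0 control verifies none appears.
* **Composition anti-correlation.** Within a fold group, the mixture of
  the other dimension's classes fluctuates, and balanced subsampling makes
  the held-out group's mixture anti-correlate with the training groups'.
  Interaction-only (non-generalizable) signal is therefore converted into
  systematic structure by the standard analysis while the cross-dimension
  analysis, which never mixes levels between training and test, stays at
  chance — the property the cross-dimension suite asserts.

## Null-study design for the calibration suites

The chance-calibration and family-wise-error suites simulate studies with
all signal gains at 0. These use 100 post-onset time points simulated as a
[0, 400) ms epoch with AR(1) noise (φ = 0.5) and no low-pass: a 6-Hz
Hamming-sinc kernel (~127 taps at 250 Hz) cannot be applied to a
100-sample epoch, and the AR(1) structure already provides the temporal
autocorrelation that the shared-relabeling permutation scheme must
respect. The chance band is ±3 binomial standard errors with
N = 120 attempts × participants; time points are autocorrelated and do
not count as independent draws.

Problem sizes used by the test suite and the acceptance script (chosen as
the package's desk-scale study conditions): chance calibration — 10
participants, 59 channels, 640 trials, 100 post-onset points, default
10-iteration decoding; family-wise error — 200 independent studies of 8
participants, 16 channels, 160 trials, 2 iterations, 200 permutations
each; recovery — 10 participants, 24 channels, 640 trials, 3 iterations,
300 permutations, full [-500, 1500) ms epochs with the 6-Hz filter and
baseline correction.

## Numerical and degenerate-input choices

* SMO: deterministic maximal-violating-pair selection, tolerance 1e-6,
  iteration cap 5000; bias from free support vectors, else the midpoint of
  the KKT interval. Degenerate training sets (all rows identical) still
  return a prediction — all classes tie and the lowest code wins.
* Standardization guards zero-variance channels by substituting sd = 1.
* `partitionBalanced()` requires every class to have at least k trials and
  names the offending class otherwise; empty target × control cells abort
  cross-dimension decoding.
* Accuracy smoothing never extends past the series (symmetric shrinkage),
  so a constant series is a fixed point and values stay inside the input
  range.
* The epoch interval is half-open in samples (closed in reported ms):
  [-500, 1500) ms at 250 Hz is exactly 500 samples, the last at +1496 ms.
* Baseline and confusion-matrix periods are half-open ms intervals;
  perception is [0, 500), maintenance [500, 1500).

## Known limitations

* The generator's linear signal-plus-AR(1) model omits 1/f background,
  spatially correlated noise, eye-movement artifacts, and realistic ERP
  waveshape; conclusions from passing tests concern the pipeline, not the
  physiology.
* Cross-dimension and previous-trial analyses inherit the leakage
  phenomena described above; on real data they are confounds to reason
  about, not bugs to fix.
* The JZS Bayes factor implementation covers the one-sample/paired case
  only.
* No reader for proprietary EEG formats is provided; epochs enter through
  the raw-float32 + JSON sidecar container (`saveEpochs()`/`loadEpochs()`)
  or the generator.
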