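---
title: "Detecting tonic–clonic seizures from wearable canine accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tonic–clonic seizures from wearable canine accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtcsdetect)
```

## The detection problem

A generalized tonic–clonic seizure (GTCS) begins with a rigid tonic phase and
continues with large-amplitude rhythmic jerking (the clonic phase). On a
harness-mounted three-axis accelerometer sampling at 50 Hz over ±8 g, the
clonic phase produces a burst of high-variance acceleration on all axes that
is unlike any routine canine movement. `gtcsdetect` frames detection as a
two-class discriminant problem in an eight-dimensional feature space and
decides each 9-s window with a single comparison of Mahalanobis distances —
no learned weights, no tuned threshold.

## Model and assumptions

**Features.** Each complete second of signal is summarised by the mean and the
coefficient of variation (CV) of the three axes and of the resultant force
$r_i = \sqrt{a_{x,i}^2 + a_{y,i}^2 + a_{z,i}^2}$: eight parameters per
second. Means capture posture (the gravity projection) and CVs capture
movement intensity relative to that posture. Bins are half-open $[k, k+1)$
seconds anchored at the trace start; a trailing partial second is dropped.

**References.** Each class is modelled by the mean vector $\mu$ and the
population variance–covariance matrix $\Sigma$ of its per-second feature
rows: the seizure reference (RDE) from every second of the tonic–clonic phase
of the training seizures, and the daily-activity reference (RDNE) from rows
pooled over fifteen movement classes, 9 s per dog per movement (135
dog-movement pairs, 1,215 rows under the default study conditions). Nine rows
is the hard minimum — the generic-invertibility threshold for an $8\times 8$
covariance — and is enforced everywhere a reference is built or loaded.

**Decision.** For an epoch of $L$ consecutive feature rows (default $L = 9$,
advanced by 1 s) each row is scored against a reference by the
dimension-scaled distance
$$d_t = \sqrt{(x_t-\mu)^\top \Sigma^{-1} (x_t-\mu) / 8},$$
and the per-row scores are aggregated — by the mean, by default — into one
epoch distance per reference. The epoch is classified *seizure* iff its
aggregated distance to the RDE is strictly shorter than to the RDNE. The rule
is invariant under any invertible affine transform of the feature space
(both $\mu$ and $\Sigma$ transform along) and under any monotone transform
applied to both distances, so only the comparison direction carries
information, not the distance scale.

The implicit statistical assumption is that each class is adequately
summarised by its first two moments — reasonable for the pooled
daily-activity cloud and for the violent but stationary clonic burst, and the
reason the method needs so little training data compared with
machine-learning detectors.

## Choices the data do not dictate

Several details of the procedure are open in principle; the package fixes
them as follows.

* **Epoch-to-reference aggregation.** An epoch is a $9\times 8$ block but a
  reference is a distribution over single rows. We score rows individually
  and average. The two obvious alternatives were rejected: flattening the
  epoch into a 72-dimensional vector needs a $72\times72$ covariance (far
  more training data than nine rows per movement can support), and scoring
  only the epoch's mean row discards within-epoch variability, which is
  exactly what distinguishes clonic movement. The scaled $\sqrt{D^2/8}$ form
  keeps reference members near 1 and epoch distances in the low single
  digits. The aggregator is configurable (`mean`, `median`, `max`); `max`
  makes the detector more trigger-happy at epoch boundaries, `mean` is the
  default and the most specific.
* **CV denominator guard.** At rest the X and Y means hover near 0 g, so a
  raw CV explodes. The denominator is floored:
  $\mathrm{CV} = s / \max(|\bar a|, f)$ with $f = 0.05$ g by default
  (`mean_floor`). The floor keeps the feature bounded and monotone in the
  spread; its value is an explicit artifact choice, logged in the feature
  attributes.
* **Population vs sample SD.** Population (divide-by-$n$) form throughout,
  for both the per-second SDs ($n = 50$ samples) and the reference
  covariances. With fixed bin sizes the choice is immaterial to any ranking;
  it is fixed for bit-reproducibility.
* **Ties.** An exact distance tie classifies as non-seizure, favouring
  specificity.
* **Covariance conditioning.** $\Sigma$ is used through its Cholesky factor
  (a triangular solve, never an explicit inverse). If the smallest eigenvalue
  is at or below $10^{-8}\,\mathrm{tr}(\Sigma)/8$, a ridge
  $\lambda = \texttt{ridge}\cdot\mathrm{tr}(\Sigma)/8$ (default
  `ridge = 0.01`) is added to the diagonal; a zero-trace covariance (all
  rows identical) falls back to $\lambda = 10^{-12}$ so degenerate inputs
  remain usable. Well-conditioned covariances pass through untouched, which
  preserves exact affine invariance in the common case.
* **Event semantics.** The streaming detector fires at the first positive
  epoch of a run once `min_consecutive_positives` (default 1 — alert without
  debouncing) is reached, then suppresses further events for `refractory_s`
  (default 60 s) measured onset-to-onset, so one seizure produces one alert.
  The debounce knob exists because shorter epochs (3 s, 6 s — both accepted
  by every function) detect seizures but admit false positives; it lets a
  user study that trade-off explicitly. The incremental path and the batch
  path share one event state machine and are property-tested for exact
  equivalence.
* **Scoring conventions.** An event matches a true seizure if its onset lies
  in $[\text{start} - 5\,\mathrm{s}, \text{end}]$ — the pre-onset tolerance
  absorbs windows that straddle the onset — with greedy one-to-one matching;
  leftovers are false positives/negatives. At epoch level, an epoch is
  seizure-truth iff at least half its span overlaps seizure intervals
  (boundary windows need *some* rule; majority overlap is the conventional
  one).

## What the simulator does and does not emulate

Every movement class is generated as *gravity/posture offset + one sinusoid
(class frequency/amplitude, random phase per axis) + white Gaussian noise*,
at 50 Hz. The shipped parameter table (`movement_params()`) covers the
fifteen daily activities used for the RDNE — static postures with zero
oscillation (standing, sitting, both lying postures), locomotion around
1.8–3 Hz, body shakes at 5 Hz with 1 g lateral amplitude — plus the two
seizure phases: a tonic posture shift with a low-amplitude 8-Hz tremor and a
clonic phase of 3 Hz, 1.8 g oscillation on all three axes. Gravity is +1 g
dorsoventral for upright postures and rotated onto the lateral axis for lying
on the side. The dog counts per movement (23 walking, 24 shaking, … 135 in
total) drive `rdne_schedule()`, which reproduces the 9 s × 135 = 1,215-s
reference-building arithmetic.

These defaults were chosen once, as plausible magnitudes for a mid-sized dog,
and are *not* measurements: no spectral characterisation of canine GTCS
accelerometry was available to fit them to. They are deliberately easy — the
clonic class sits ≥ 6 pooled standard deviations (in practice ≥ 25) from
every daily activity in feature space, which the test suite asserts. Passing
the synthetic benchmarks therefore demonstrates that the *pipeline* is
correct (features, covariances, distances, windowing, event logic, streaming
equivalence), not that the method would achieve the same sensitivity or
specificity on real recordings, where class overlap, inter-dog variability,
postural drift and sensor displacement are all harsher. The displacement
scenario (`apply_displacement()`) rotates the sensor frame mid-recording and
is the one adversarial case included: rotations preserve the resultant force
but shift the per-axis features, which measurably inflates distances to
references built in the upright frame — the known false-positive mechanism
for this class of detector.

## Numerical and degenerate-input behaviour

Uniform sampling is validated on read (any timestamp step deviating from the
nominal interval by more than 20 % is an error naming the row — never a
silent resample); out-of-range samples are clipped to the device range with a
warning, as a real sensor would saturate. Per-second moments are computed by
grouped sums ($E[x^2]-\bar x^2$, clamped at 0 before the square root).
Traces shorter than 1 s are errors; streams shorter than one epoch yield
empty results, not errors. Reference persistence uses JSON with 17
significant digits so a save/load round trip is elementwise exact. All
simulator randomness is seed-scoped: a seeded call restores the session RNG
state afterwards and identical seeds give bit-identical traces.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the full-scale windowing
arithmetic (a 40,545-s feature stream → 40,537 sliding 9-s epochs, classified
in one vectorised pass), a 1,000-system cross-check of the factorized
Mahalanobis solve against the explicit-inverse quadratic form, 10,000-epoch
two-Gaussian classification, and event-level recovery of one to three 30-s
seizures embedded in synthetic monitoring days of roughly 10–15 minutes each
— sizes chosen to exercise every code path at full arithmetic scale while
keeping a complete run in the tens of seconds.

## Known limitations

* Two classes only; the framework does not attempt focal seizures or
  fine-grained activity recognition.
* No probabilistic calibration: distances support a decision, not a
  seizure probability, and no ROC analysis is provided (the decision rule
  has no threshold to sweep, although the distance pairs would permit one as
  an extension).
* References are cohort-level; per-dog individualized references are out of
  scope.
* The simulator's single-sinusoid classes understate real within-class
  variability; synthetic specificity numbers are optimistic by construction.
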