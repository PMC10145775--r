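---
title: "Methods: from a lower-back IMU recording to an annular gait summary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from a lower-back IMU recording to an annular gait summary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitview)
```

gaitview condenses a six-channel lower-back IMU recording of a
semi-free-living walking protocol into a small, readable summary: the
recording is segmented into homogeneous activity regimes, each regime is
labeled walking / sedentary / non-sedentary, walking regimes are scored on
four gait criteria against a healthy reference, and the result is drawn as
an annular chart. This vignette explains each model, its assumptions, the
tunable parameters, and the numerical choices, in the order the pipeline
runs them.

## Signal model and preprocessing

A recording holds three accelerations (g) and three angular velocities
(deg/s) on the anatomical axes — craniocaudal (CC), mediolateral (ML),
anteroposterior (AP) — sampled at 100 Hz. All six channels are bandpass
filtered between 0.5 and 5 Hz with a 4th-order Butterworth filter, applied
forward and backward (`signal::filtfilt`) so that no stage downstream sees
phase distortion; the price is a magnitude response of effective order 8,
which we accept because the autocorrelation peak lags used by the gait
criteria must not move. Everything downstream — segmentation features,
classification features, criteria — consumes the filtered recording.

Change-point detection does not run on raw samples but on a short-time
Fourier representation of the two channels most sensitive to activity
changes: the craniocaudal angular velocity and the anteroposterior
acceleration. Each is standardized to zero mean and unit variance over the
whole recording (per-regime statistics cannot exist before segmentation),
cut into 3 s Hann windows hopping by 0.1 s, and reduced to the magnitudes of
the bins strictly inside (0, 5) Hz. At 100 Hz and a 300-sample window the
bin spacing is 1/3 Hz and the open band keeps exactly 14 bins per channel;
the two blocks concatenate to a 28-dimensional frame. Inclusive band edges
would give 16 bins; the open interval is what makes the dimensionality come
out at 28. The Hann window is our choice (leakage control in a narrow
band); the bin count does not depend on it.

## Penalized change-point detection

Frames are modeled as a piecewise-constant mean signal plus noise. For
breakpoints $t_1 < \dots < t_K$ the empirical quadratic risk is the sum of
within-segment squared deviations from segment means, and the working
objective is the penalized risk $R(y, \{t_k\}) + \beta K$. `pelt_segment()`
returns its exact global minimizer over all segmentations with segments of
at least `min_size` frames (default 2 frames = 0.2 s): the number of
breakpoints is an output, not an input. The solver is a pruned dynamic
program (PELT) in C++; segment costs come from cumulative sums, so each
evaluation is O(d).

Two implementation notes. Internally segments are half-open, 0-based
`[t_k, t_{k+1})`; only the I/O boundary speaks in seconds. And the textbook
pruning rule ("discard s once $F(s) + C(s,t) > F(t)$") is subtly unsound
when a minimum segment length is enforced: the path through $t$ that
dominates $s$ is infeasible for targets closer than `min_size` frames. The
solver therefore defers each removal by `min_size` steps, which restores
exactness; `brute_force_segment()`, an unpruned O(n²) dynamic program in
pure R, certifies this on random instances in the test suite, comparing
attained risks so that ties among optima do not produce false alarms. Ties
are broken deterministically toward the earliest admissible predecessor,
i.e. toward fewer, earlier breakpoints.

A breakpoint's time is the center of the frame at which the new regime
starts (`frames_to_seconds()`): frame $k$ maps to $0.1k + 1.5$ s. The
round trip seconds → frame → seconds errs by at most half a hop.

## Supervised calibration of the penalty

The penalty $\beta$ decides the segmentation scale, and the right scale is
defined by expert annotations, not by theory. Given annotated recordings,
`calibrate_penalty()` minimizes the mean excess penalized risk
$\tfrac1N\sum_i [R_\beta(y^{(i)}, \text{truth}^{(i)}) -
R_\beta(y^{(i)}, \hat t^{(i)})]$, where $\hat t^{(i)}$ is the solver's
optimum at that $\beta$. Each term is non-negative by optimality — the test
suite checks this along the whole search trace — and small exactly when the
solver reproduces the expert's scale. Annotated timestamps are snapped to
the nearest frame.

The objective is piecewise constant in stretches (the solver's output
changes at discrete $\beta$ thresholds), so a pure golden-section search
can stall on a flat step. We therefore seed with a 25-point grid on
$\log_{10}\beta$ spanning eight decades around the signals' mean per-frame
variance, then let Brent's method (`optimize()`) refine the best bracket,
keeping whichever is better. A per-signal mode (`per_signal = TRUE`) fits
one penalty per recording and aggregates by the median; the joint mean is
the default.

## Regime classification

Segmented regimes are classified at the regime level — regimes are
approximately stationary and much longer than typical sliding windows, so
features are computed on more data. `extract_features()` produces 129
features per regime: for each of the six channels, 21 temporal and spectral
descriptors (moments, extrema, unbiased SD and variance, coefficient of
variation, RMS, the power and location of the two dominant periodogram
frequencies, nearest-rank percentiles 75/25/85/15/95/5, and the 75/25/85/15
percentiles of the central two-thirds of the regime), plus the two
craniocaudal autocorrelation peaks shared with the scoring stage and the
mean acceleration vector magnitude. Percentiles use the nearest-rank rule
(the ⌈p·n/100⌉-th sorted value, floored at rank 1). The second dominant
frequency is the largest periodogram local maximum at least 0.2 Hz away
from the first — without the exclusion it degenerates to the bin adjacent
to the first peak. Degenerate inputs are imputed rather than fatal: a
zero-variance channel gets CV = 0 and zero spectral features; peaks fall
back to 0 when the autocorrelation is undefined.

The classifier is a cascade of two soft-margin linear support-vector
machines (cost 1, `e1071`) on standardized features projected onto the
smallest set of principal components holding at least 99% of the cumulative
explained variance, fitted on training regimes only. Stage 1 separates
walking from everything else; stage 2 sees only non-walking regimes and
separates sedentary (motionless: leaning, standing, sitting) from
non-sedentary (moving but not walking: door opening with a turn, short
stairs). A regime predicted walking never reaches stage 2. Predicted
regimes shorter than one second — possible since the solver's minimum
segment is 0.2 s — have their feature window symmetrically widened to 1 s
of context; the reported span is untouched.

## Gait criteria and healthy-reference scoring

Each walking regime is scored on four standard criteria:

* **Stability** — `rmsr_ml`, the mediolateral RMS divided by the
  three-axis RMS magnitude; lower is better (mediolateral energy indexes
  postural instability).
* **Sturdiness** — `rmsr_ap`, the anteroposterior RMS ratio; higher means
  more vigorous step impulsion. The squared ratios over the three axes sum
  to one by construction, which the tests assert at 1e-12.
* **Symmetry** — `p1cc`, the autocorrelation of craniocaudal acceleration
  at the one-step lag: alike left and right steps give a high peak.
* **Steadiness** — `p2cc`, the same at the two-step (one-stride) lag:
  alike consecutive strides give a high peak.

The autocorrelation is computed via the Wiener–Khinchin route (FFT,
squared magnitude, inverse FFT), zero-padded to at least twice the length
to avoid circular wrap, on the mean-removed series, with the unbiased
$1/(n-\mathrm{lag})$ correction and normalized to 1 at lag zero. Peaks are
searched in cadence-anchored lag windows — $[0.5, 1.5]$ step periods for
the one-step peak, $[1.5, 2.5]$ for the two-step peak, with the cadence
taken from the dominant craniocaudal frequency in 0.8–3.5 Hz — because a
global "first local maximum" rule is captured by noise lobes below the
step lag.

Two numerical choices matter on short windows and are worth stating
plainly. First, peak *heights* in the pipeline are evaluated as the
support-matched correlation coefficient at the ACF-localized lag,
spline-interpolated between integer lags: the unbiased ACF estimator
averages its numerator over $n-\mathrm{lag}$ samples but its normalizer
over $n$, which makes peak values wobble by $O(1/\text{cycles})$ on 3 s
windows even for perfectly periodic input, and the step period is almost
never a whole number of samples. On long stationary regimes the two
estimators agree; on the short degraded windows of the robustness study
only the support-matched version is stable enough to reflect the signal
rather than the estimator. Second, criteria windows exclude small edge
guards (0.1 s for the RMS ratios, 0.3 s for the peaks): regime spans abut
transitions whose content belongs to neither regime, and the zero-phase
0.5 Hz high-pass edge smears that content about half a second inward.
Correlations are degraded at first order by cross-regime phase mixing,
hence their wider guard; energy ratios are touched only at second order
and keep more cycles instead.

The healthy model is deliberately simple: per criterion, the mean and SD
over all healthy walking regimes define a z-score, and the display bounds
are the 10th and 90th percentiles of the z-scored healthy values — no
normality is assumed, so the bounds are near ∓1.28 only incidentally. By
construction about 80% of healthy regimes fall inside the bounds, up to
percentile interpolation at small n. Scores are oriented so that higher
is always better (the stability ratio is negated) and binned into five
display categories; "slightly" below or above extends half the healthy
inter-percentile range past a bound, a width the source material names but
never quantifies — our choice, fixed here.

## The synthetic protocol generator

No cohort data ships with the package, so every stage is exercised on a
synthetic emulation of the annotated protocol: laps of a hospital corridor
with activities at the end of each lap, exactly 6 minutes, with ground
truth changepoints at the block joins. The default sequence is W1 (50 s),
A1 door opening + 90° turn (15 s), W2 (40 s), W3 (40 s), A2 short stairs
(25 s), A3 leaning (20 s), A4 standing (20 s), A5 sitting (30 s), W4
(60 s), W5 (60 s) — durations are our choice (the protocol's published
description fixes the order and the 6-minute total, not the split); the
minimum changepoint spacing of 15 s comfortably exceeds the 3.5 s
evaluation margin, as the margin definition requires.

Walking blocks are a harmonic series (fundamental plus two harmonics) at
the step frequency on the craniocaudal axis, a stride-frequency (half
cadence) oscillation on the mediolateral axis, and a step-frequency
oscillation on the anteroposterior axis — simple enough that spectra and
autocorrelations have closed forms against which the tests check. Four
knobs map monotonically onto the criteria: `amp_ml` raises the stability
ratio, `amp_ap` the sturdiness ratio, `asymmetry_delta` adds a
stride-frequency admixture to the craniocaudal channel that lowers the
one-step peak while leaving the two-step peak nearly unchanged, and
`timing_jitter_sd` jitters step periods (piecewise-linear phase through
jittered step boundaries), lowering the two-step peak. These links are
verified end-to-end through filtering and slicing, not just on raw blocks.

The generator's realism decisions all exist to make the protocol carry the
information a real one carries. Walking legs vary between laps (±7%
cadence, ±20% amplitudes, per-block asymmetry and jitter factors), so
walking→walking transitions are sustained spectral shifts, as they are when
a subject turns a corner and changes pace — without this W2|W3 and W4|W5
would be invisible. Turns are 1 s Gaussian yaw pulses centered on the
walking block boundaries, the transitions flagged as hardest in this
protocol family. Sedentary activities carry distinct sustained
micro-activity levels (leaning 0.035 g > standing 0.015 g > sitting
0.004 g, with matching angular-velocity content) because the 0.5 Hz
bandpass erases slow postural sway, and every activity block opens with a
~0.8 s postural transient (sitting down, grabbing a door) — without these,
still-to-still boundaries would be information-theoretically undetectable
by any mean-shift detector, which no annotated real protocol is.
Non-sedentary blocks are band-limited noise under dense smooth burst
envelopes: nonstationary at sub-second scale, homogeneous at the 3 s
window scale. Blocks join through 0.1 s raised-cosine cross-fades with the
ground-truth changepoint at the fade midpoint. White sensor noise
(`noise_sd`, default 0.02 g, angular channels scaled ×30) is set so that
segmentation at the calibrated penalty is clearly solvable without being
trivial.

Healthy cohort subjects draw cadence in 1.7–2.1 Hz, asymmetry in 0–0.1,
step-timing jitter in 4–25 ms (step-time CV of roughly 1–5%, the healthy
range), and mild amplitude variation around the defaults. Pathological
subjects degrade exactly one aspect, cycling over four subtypes: stability
(mediolateral amplitude at least doubled), sturdiness (anteroposterior
amplitude shrunk to ~a third), symmetry (asymmetry 0.4–0.6), steadiness
(jitter 50–80 ms). The default 70/30 healthy/pathological split mirrors a
21-versus-9 cohort, and subject-wise 3-fold cross-validation splits
balance the health flag so a 30-subject cohort yields folds of 7 healthy
plus 3 pathological subjects.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: biomechanical waveform detail (no double-support
asymmetries, no heel-strike transients), soft-tissue and sensor-mounting
artifacts, stair-specific morphology, gravity leakage through imperfect
axis alignment, and free-living confounders such as shuffling or carrying
loads. Results on the synthetic cohort bound what the machinery can do
when its assumptions hold; they are not clinical validation.

## Evaluation machinery

Segmentation is scored with margin-based precision, recall and F1: a
predicted changepoint is a true positive if it is within 3.5 s of an
unmatched true changepoint, matched greedily by increasing time difference,
one-to-one. Greedy matching coincides with optimal assignment when the
margin does not exceed the minimum true spacing, which the protocol
guarantees. An empty prediction list scores precision 0 rather than NaN;
two empty lists score 1. The joint segmentation+classification quality is
a 3×3 row-normalized confusion matrix at the original 100 Hz sample scale,
each sample labeled by the regime containing it.

The robustness study recomputes the criteria of each walking regime on ten
degraded windows — the full regime, the first 3 / 3.5 / 4 / 5 s, the first
40%, 40% starting at 20 / 30 / 40% of the duration, and the last 40% — and
summarizes the per-regime spread (median, IQR) for comparison against the
healthy cohort's spread, the package's analogue of judging whether feature
boxes "stay tight" under segmentation errors.

## Problem sizes and determinism

The test suite and acceptance script run entirely on generated data: ten
6-minute annotated recordings for calibration (five to fit, five held
out), a 10-subject cohort for the cross-validated pipeline and the healthy
model, 200 random instances for solver certification, and 20 seeds per
knob for the monotonicity checks — sizes chosen so the whole suite
completes in a few minutes on one core while every check still has
statistical teeth. All randomness flows through explicit integer seeds;
recordings are bit-reproducible given (configuration, knobs, seed), and
the SVG renderer emits byte-identical files for identical inputs, which
the golden-file test pins down.

## Known limitations

The solver's cost family is fixed to mean shifts of spectral frames; slow
drifts within an activity can be over-segmented. The cadence estimate
assumes the dominant craniocaudal frequency in 0.8–3.5 Hz is the step
frequency, which can lock onto the stride frequency for extremely
asymmetric gaits (admixture near 1). The healthy model treats regimes as
exchangeable, ignoring within-subject correlation, so its percentile
bounds are slightly anti-conservative for cohorts with few subjects. And
the five-level display palette imposes hard bin edges on what is really a
continuous scale; regimes near a bound can flip bins under resegmentation.
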