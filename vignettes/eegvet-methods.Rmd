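---
title: "Tracking gaze from EEG: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking gaze from EEG: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`eegvet` estimates on-screen gaze position from multichannel EEG alone.
This vignette explains the underlying model, the algorithmic and numerical
choices the package makes where the method leaves them open, what the
bundled simulator does and does not emulate, and the limitations a user
should keep in mind.

## The generative model

The eye is a strong electric dipole (cornea positive), so eye rotation
produces large, spatially stereotyped potentials across the scalp. The
recorded EEG is modeled as an instantaneous linear mixture

$$x(t) = A\,s(t),$$

where $x(t)$ are the $n$ channel time series, $s(t)$ are $n$ unobserved
sources, and $A$ is an unknown mixing matrix. Two of the sources — the
horizontal and vertical ocular components — are assumed affine in the gaze
coordinates. The whole method rests on recovering those two sources
blindly, recognizing them, and calibrating the affine map per individual.

## Stage 1: second-order blind identification (SOBI)

`sobi()` recovers $W = A^{-1}$ by exploiting the sources' distinct
*temporal* structure: for mutually uncorrelated sources, every time-lagged
covariance matrix $C(\tau) = \langle x(t)\,x(t+\tau)^\top \rangle$ is
diagonalized by the same unmixing. Concretely:

1. **Whitening.** The mean-removed data are projected onto the principal
   subspace and scaled so the zero-lag covariance is the identity.
   Eigenvalues below $10^{-12}$ of the largest are dropped and the retained
   rank is reported.
2. **Lagged covariances.** Symmetrized covariance estimates
   $\tfrac12(C(\tau)+C(\tau)^\top)$ (biased, $1/T$ normalization, common
   summation window $T = N - \max\tau$) are computed at delays of
   1–350 ms, dense at short lags; at 500 Hz the 41 millisecond values
   deduplicate to 36 distinct sample lags (delays are rounded to the
   nearest sample, minimum one).
3. **Joint approximate diagonalization.** One orthogonal matrix is fitted
   to all lagged covariances at once by Givens-rotation (Jacobi) sweeps,
   each rotation exactly minimizing its pair's contribution to the summed
   squared off-diagonal mass, so the criterion never increases.

**Stopping rules.** Classical angle-based stopping (finish when every
rotation in a sweep is below a tolerance) is kept, with a data-scaled
default of $1/(100\sqrt{N})$ radians. It is, however, insufficient on
real-sized problems: with 64 channels and ~20 structured sources, the
whitened space contains a noise-dominated subspace in which pair rotations
are essentially indifferent — the algorithm keeps producing
$\sim 10^{-2}$ rad rotations forever while the criterion is flat. The
package therefore also stops when a full sweep reduces the criterion by
less than $10^{-4}$ of its current value, or when the criterion has fallen
below $10^{-14}$ of its initial value. The plateau rule is relative to the
*current* criterion, so it never fires early on exactly diagonalizable
inputs (where convergence is quadratic and each sweep still shrinks the
criterion by orders of magnitude). Typical sessions converge in about
10 sweeps.

**Fixing the BSS indeterminacies.** Scale, sign, and order of blind
sources are arbitrary. The package pins them: each column of $A$ has unit
Euclidean norm with its absolutely largest element positive (the inverse
scaling absorbed into the source), and components are ordered by
decreasing source variance. Every downstream quantity is either invariant
to these conventions (DANS indices, predictions) or defined relative to
them, which is what makes results deterministic and testable.

SOBI runs once on the continuous, pre-filtered recording of the whole
session (calibration and test tasks together). An identifiability point
discovered with the simulator and worth knowing: if only the dot-tracking
task is recorded, the horizontal and vertical ocular sources have almost
identical autocorrelation shapes (identical trial timing; amplitude
sequences differing only through the cosine/sine of target direction), so
the rotation *within* their two-dimensional subspace is weakly determined
and SOBI may return mixtures of the two. Any session segment in which
horizontal and vertical eye movements have different dynamics — here, the
horizontal-only smooth pursuit task — makes the pair spectrally distinct
and the rotation well determined. (The gaze regression is robust to this
either way, because both component amplitudes enter both equations.)

## Stage 2: ocular component identification (DANS)

Each component is scored by the product of two indices per axis.

* **Discriminant index.** The saccade-related potential (SRP) amplitude is
  the median of the trial-averaged, baseline-corrected component response
  within 200–1200 ms after target onset (baseline: mean over the 500 ms
  before onset). For the horizontal axis the signed difference
  $d_i = \mathrm{SRP}_{right,i} - \mathrm{SRP}_{left,i}$ over the
  long-saccade (outer-ring, 12.2°) trials is normalized as
  $DI_i = |d_i| / \max_j |d_j|$; analogously up/down for the vertical
  axis. The absolute value in the normalization is a deliberate choice:
  source separation leaves component signs arbitrary, so ranking by a
  signed maximum would make selection depend on an arbitrary convention.
  The direction information survives inside $d_i$.
* **Similarity index.** Pearson correlation across channels between the
  component's scalp projection (its column of $A$) and an analytic
  prototype of the ocular topography — left/right-antisymmetric and
  frontally peaked for the horizontal component, frontal-maximal with an
  anterior–posterior decay for the vertical one — taken in absolute value
  and normalized by the maximum; values below 0.5 are set to exactly 0,
  removing implausible candidates from consideration.

The component with the largest nonzero $DI \cdot SI$ wins each axis. The
two axes must select *different* components; if one component tops both
lists, the axis with the larger score keeps it and the other re-selects
from the remainder (ties break toward the lower component index). An axis
with no nonzero score raises an explicit "no ocular component found"
error rather than guessing.

## Stage 3: the gaze regression

Calibration uses *single-trial* SRP amplitudes (same window and baseline
as above, computed per trial rather than on the trial average) of the two
selected components at all 32 dot-task trials, regressed on the known
target coordinates by ordinary least squares with intercept. Per-trial
amplitudes are required because the regression needs within-session
variation; the average SRP would collapse each condition to one point.
Reported diagnostics are the multiple correlation per axis and two-sided
t-test p-values per predictor ($n-3$ degrees of freedom), with no
multiple-testing correction — they are descriptive, not inferential.

For continuous tracking, per-sample amplitudes are referenced to the mean
component level over each trial's pre-target fixation interval, so every
trial's prediction starts from the intercepts (the screen center the
participant fixates). This baseline convention is the package's own: some
per-sample reference is required and the fixation interval is the only
moment with known gaze. A 25 ms moving average suppresses sample-level
noise; it is far below the time scale of the 60 Hz-class evaluation grid,
so it does not bias trajectory shape.

## Evaluation geometry

All angular quantities place the eye on the normal through the screen
center at the viewing distance (600 mm by default; the head is assumed
fixed, as with a chinrest). The angular separation between two on-screen
points is computed by the spherical law of cosines on the slant triangle,

$$\cos\gamma = \frac{c_1^2 + c_2^2}{2c_1c_2} - \frac{d^2\,c_1 c_2}{2D^2},$$

with $c_i$ the cosine of each point's visual angle from center, $d$ their
on-screen distance, and $D$ the viewing distance. This expression is
algebraically exact (not small-angle), and the tests verify it against the
3-D eye-vector angle to $10^{-9}$ degrees over random point pairs,
including off-center ones.

* **Accuracy** = mean over trials of the angular separation between the
  target and the trial's mean measured fixation position (arithmetic mean
  across trials; an aggregation the package fixes since several are
  defensible).
* **Precision** = RMS of angular separations between successive fixation
  samples.
* **Pursuit RMSE** = per-axis RMS difference between predicted and target
  trajectories, both linearly resampled onto 180 uniform points per trial
  (the trial window runs from step-target onset to 256 ms past motion
  end); 180 points corresponds to 3 s of a 60 Hz eye-tracker grid.
  Reported in mm, with degree conversion helpers.

The saccade-test fixation window is 200–256 ms after step-target onset:
after typical saccade latency, before target motion begins.

## The simulator: what it emulates, and what it does not

`simulate_session()` generates the full study design: a 32-trial
dot-tracking task (8 directions × 6.1°/12.2° rings, 2 repetitions,
500–1000 ms fixations, 1.5 s targets) and a 64-trial smooth-pursuit task
(8 trials per speed {1, 5, 9, 19}°/s × direction {left, right}; 23 mm
step opposite the motion, 256 ms static, 512 ms motion, 256 ms static,
600–900 ms fixations), on a 504 × 285 mm screen at 600 mm.

Behavior: saccade latencies are truncated-normal (180 ± 30 ms, floor
100 ms), saccade displacement profiles are minimum-jerk with duration
40–80 ms scaled by amplitude, smooth pursuit follows the target with gain
0.9 and 100 ms lag plus a catch-up saccade onto the stopped target, and
fixation carries 0.1° jitter (white horizontally, AR(1)-smoothed
vertically, mirroring the slower spectral content of vertical fixational
movement). These are conventional oculomotor magnitudes, fixed once in
`simulation_spec()`.

Forward model: the two ocular sources are exactly affine in the gaze
coordinates (gain set so their RMS is `ocular_ratio` = 3 times the
unit-RMS background sources); 20 background sources (alpha-band
oscillators with drifting envelopes, AR(2) processes with spread
resonances, one slow drift) provide the stationary, spectrally distinct
activity SOBI needs; mixing columns are the prototypical ocular maps
perturbed by 10% noise plus smooth random maps; white sensor noise is
added (SD 0.1 in source units).

What is *not* simulated — and therefore what passing tests do **not**
demonstrate about real recordings: eye blinks and lid movement (which are
known to contaminate the vertical component in real recordings and are
the main caveat for the vertical axis), head movement, electrode drift
and impedance changes,
muscle and cardiac artifacts, nonstationary brain activity, and a
realistic volume-conduction head model (scalp fields are schematic
templates, not BEM solutions). The simulator shows the algorithmic chain
is correct and self-consistent under its stated assumptions; performance
numbers on simulated sessions are expected to be better than on human
data, and they are.

## Numerical choices

* **Filters.** The 0.1 Hz high-pass is a true order-4 Butterworth realized
  as two cascaded biquad sections (the transfer-function form is
  ill-conditioned with poles this close to $z = 1$), the 50 Hz notch a
  standard biquad with Q = 30; both run zero-phase (forward–backward) so
  saccade-locked epochs keep their latency, with 4000-sample reflective
  padding and channel means removed first so edge transients are
  negligible. Zero-phase squaring puts the half-power point of the
  cascade at the nominal cutoff.
* **Epoch windows** are converted from ms to samples by rounding; the
  baseline window is right-open at the onset sample.
* **Degenerate inputs** fail loudly: rank-deficient calibration designs,
  epochs extending beyond the recording, missing trial conditions,
  empty baselines, off-screen coordinates, non-finite samples, and
  channel/label mismatches are all explicit errors, never silent repairs.
* **Performance.** The joint-diagonalization sweeps, lagged covariances,
  and the zero-phase filter are compiled (RcppArmadillo); a full session
  (about 4 minutes of simulated 64-channel data, ~120k samples)
  calibrates in a few seconds.

## Problem sizes used by the test suite

Unit tests run on small constructed fixtures (hundreds to tens of
thousands of samples). The end-to-end checks use full-size sessions: the
source-recovery fixture is 6 AR(2) sources over 60 s at 500 Hz across ten
seeds; the selection study runs 40 complete two-task sessions; the
tracking check calibrates on 32 dot trials and evaluates on 64 pursuit
trials of one session. These sizes were chosen as the smallest at which
the quantities of interest are stable across seeds.

## Known limitations

* Vertical tracking rests on the same machinery as horizontal but is
  validated only against a simulator without blinks; on real data the
  vertical component is known to be the weaker one.
* The linear gaze map ignores the mild tangent nonlinearity between eye
  rotation and screen position; over ±12° it is a good approximation, and
  the calibration absorbs most of the residual.
* One SOBI run serves the whole session; electrode movement or
  re-gelling between tasks would break the shared unmixing assumption.
* The accuracy/precision contract assumes the eye on the center normal;
  head-free recording is out of scope.
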