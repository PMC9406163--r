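---
title: "Methods: scoring and validating a robot-based sensory processing assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and validating a robot-based sensory processing assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assessment

`sensproc` analyses a three-step assessment of upper-limb sensory
processing administered on a planar end-point robot. Per trial, a
participant (1) explores a flat geometric shape — either *passively*, with
the robot driving the affected/non-dominant hand along the shape, or
*actively*, by moving the hand inside a narrow zero-force corridor bounded
by stiff virtual walls; (2) *reproduces* the shape with the contralateral
arm, without mirroring, within 15 s; and (3) *identifies* the explored
shape among six on-screen options, rating answer certainty on a 0–3 Likert
scale. Each condition comprises 15 scored trials preceded by 5 practice
trials (practice is generated but never scored).

Shapes are simple polygons — triangles, tetragons and pentagons — traced
from a common start point 20 cm in front of the shoulder, with every side
between 2.92 and 14.14 cm. Because the original shape catalogue is not
published, `generate_shape_library()` reproduces only these published
constraints, by seeded rejection sampling of star-shaped polygons: the
class mix (5 shapes per class by default), the side-length bounds, a shared
start vertex at the origin, simplicity, and a workspace radius (25 cm
default). The library is a pure function of its arguments and is written to
a JSON file alongside every pipeline run.

## What the simulator emulates

No public dataset exists for this assessment, so the package ships a
synthetic-session generator whose defaults encode the study conditions:

* **Passive exploration** follows a minimum-jerk arc-length profile
  $s(t) = P\,(10\tau^3 - 15\tau^4 + 6\tau^5)$, $\tau = t/T$, whose peak
  tangential speed $1.875\,P/T$ is set to 0.67 m/s; speed is zero at both
  endpoints; sampling is 1 kHz, with the exact vertex-passage instants
  added to the grid so the recorded polyline carries the corners and its
  chord length equals the traversed arc length.
* **Active exploration** traverses each polygon side at a speed drawn from
  a truncated normal with mean 0.04 m/s and SD 0.01 m/s (the reported
  self-paced exploration speed), with smoothed lateral noise clipped to the
  ±0.1 cm zero-force corridor. The virtual wall (6000 N/m stiffness) is
  represented purely kinematically as this clipping; no force simulation is
  attempted, since only kinematics enter the analysis.
* **Reproduction** applies a similarity transform to the (possibly
  confused) shape — scale drawn around a mean of 1.41, the size
  overestimation observed in both groups; rotation around 0° — plus
  per-vertex jitter and smoothed path noise, then traverses it with a
  minimum-jerk profile (default peak 0.25 m/s) within the 15 s limit.
  Start and end stay anchored at the start point.
* **Identification** is correct with probability
  $1 - p_\text{err}$, reduced to a quarter of that on shape-confused
  trials; errors prefer same-class distractors 2:1; certainty is drawn from
  a group-specific distribution and shifted one level down with probability
  0.5 on errors.

Group profiles differ only in noise and error parameters: the stroke
defaults dominate the healthy defaults (larger rotation/jitter/path noise,
more confusion and identification errors, slightly lower certainty), while
the mean reproduction scale of 1.41 is common to both groups, matching the
reported equality. The free constants that the source protocol does not
print (rotation SD, jitter, confusion and error probabilities, certainty
distributions) were fixed once by closed-form expectation arithmetic so
that healthy cohorts identify roughly low-60s percent of shapes and stroke
cohorts mid-40s percent, and certainty means land near 2.16 (healthy) and
1.99 (stroke); they are exposed in `participant_profile()` and are not
treated as ground truth.

**Between-participant structure.** The protocol's source material does not
describe participant-level variance, so the simulator adopts one latent
*ability* per participant, $a \sim N(0,1)$: all noise SDs are multiplied by
$e^{-0.35a}$ and the confusion/error probabilities are shifted by $-0.6a$
on the logit scale. This single shared cause induces the positive manifold
that the one-factor analysis downstream is designed to recover. It is a
modelling choice: real data may carry multi-factor structure, serial
learning effects, fatigue, or hemisphere-specific deficits, none of which
are simulated — so passing tests demonstrate internal consistency of the
pipeline, not fidelity to any particular patient population. Seeds are
split deterministically per participant and trial, so cohorts are
reproducible under reordering.

## Preprocessing

Phase segmentation follows a velocity rule: a phase starts at the first
sample where the hand is outside a start disc *and* moving at ≥ 0.02 m/s,
and ends at the first later sample back inside the disc. Two quantities the
rule needs but the protocol leaves implicit are config-exposed in
`segmentation_config()`: the start-disc radius (1.0 cm, safely below the
2.92 cm minimum side) and a minimum phase duration guarding against
immediate re-entry at onset. The guard defaults to 0.1 s: it must sit
*below* the shortest legitimate phase, and the robot-driven traversal of
the smallest legal shape (perimeter 3 × 2.92 cm at 0.67 m/s peak) spends
only ≈ 0.12 s between leaving and re-entering the start disc — a longer
guard silently converts the fastest passive phases into "no return"
fallbacks and misaligns the two phases' crops. Speed uses central finite differences at
interior samples (order $h^2$), one-sided at the ends; no filtering is
applied, since none is described for the original analysis. If the hand
never returns, the crop extends to the last sample and is flagged rather
than discarded.

Both phases are then normalized in time: linear interpolation of $x(t)$ and
$y(t)$ onto 1000 uniformly spaced time points, which removes speed
differences between exploration and reproduction. The length 1000 is a
package choice (the original length is unstated) fixed for both phases so
the per-axis signals are comparable and the alignment costs have a stable
scale.

## The four scoring parameters

* **Cross-correlation** (per axis): both signals are mean-centered and
  $c(\ell) = \sum_t a_t b_{t+\ell} / \sqrt{\sum a^2 \sum b^2}$ is maximized
  over all lags. The cited generic routine neither centers nor picks a lag
  by default; centering stops positional offsets from inflating values
  toward 1, and the max over lags tolerates onset misalignment. A
  `lag = "zero"` mode (plain Pearson correlation) is available since the
  original convention is not printed.
* **Dynamic time warping**: classic dynamic programming with Euclidean
  local cost in cm, steps {(i−1,j), (i,j−1), (i−1,j−1)}, no window; the
  value is the accumulated cost along the optimal path (cm·samples). The
  step pattern is likewise unstated in the source; the classic symmetric
  pattern is used and validated against exhaustive path enumeration.
* **Procrustes superimposition**: the reproduction is optimally translated,
  rotated (reflection permitted, but the determinant is reported so mirror
  reproductions are detectable) and scaled onto the exploration via the SVD
  of the centered cross-covariance; $d$ is the minimized residual divided
  by the centered sum of squares of the exploration, hence
  similarity-invariant, 0 iff the shapes match exactly. The reported
  `scale` is $\lVert R_c\rVert_F / \lVert E_c\rVert_F$ — reproduction size
  relative to exploration — so the familiar 1.41 means "drawn too large".
* **Identification**: percent correct over valid trials, plus mean
  certainty. Trials whose segmentation fails are dropped, counted in
  `n_valid_trials`, never imputed.

Noise-free sessions sit at the analytic fixed point (cross-correlation 1,
DTW 0, Procrustes $d$ 0); with simulated noiseless trajectories the DTW
retains a small discretization floor (different phase durations imply
different 1 kHz sample grids, worth ~10⁻² cm·samples after interpolation),
while $d$ and the cross-correlations still agree with the fixed point to
well below 10⁻⁵ when the reproduction is at scale 1. When it is enlarged,
the fixed 1 cm crop disc spans a smaller *relative* arc fraction of the
reproduction than of the exploration, shifting the time-normalized
correspondence by a percent or two of arc: single noise-free trials at
scale 1.41 recover scale ≈ 1.39–1.40 with $d$ of order 10⁻³–10⁻². This
crop-asymmetry bias is inherent to absolute-radius segmentation followed by
time normalization (real robot data carry it too); at cohort level it
amounts to well under 0.01 on the mean recovered scale.

## The one-factor ability score

DTW and Procrustes $d$ grow when performance worsens; they are negated
before factoring so all five parameters point the same way and the factor
reads "higher = better". This matches the published all-positive loading
table, which can only arise under such an orientation (or a reflected
factor). On the oriented, standardized healthy table the package runs
iterated principal-axis factoring: communalities start at squared multiple
correlations, and each step eigendecomposes the reduced correlation matrix
and updates communalities to squared loadings, until the largest change is
below 10⁻⁶ (cap 200 iterations; non-convergence is flagged, not fatal).
The raw correlation eigenvalues are returned for the scree check.

Two scoring rules coexist deliberately, mirroring the published procedure:
healthy participants get **regression scores** $Z R^{-1} \lambda$ (mean
exactly 0 in the fitting cohort, variance $\lambda' R^{-1} \lambda \le 1$),
while patients get the **loading-weighted mean of z-scores** computed
against healthy means and SDs, $\sum_i \lambda_i z_i / \sum_i \lambda_i$.
Their scales differ (the weighted-z score of a patient one healthy SD worse
on everything is exactly −1); both are linear in the oriented z-scores and
correlate near unity on the same rows. Users wanting a scale-consistent
comparison can score both groups with `weighted_z_factor_scores()`.

Normative cutoffs follow the published logic: per parameter and for the
factor score, the 95% confidence interval of the *healthy mean* (t
quantile; at n = 60 the difference from the normal quantile is negligible),
with abnormality flagged only on the worse side — below the interval for
cross-correlations, percent identified and the factor score, above it for
DTW and Procrustes $d$. Note this is an interval for the mean, not a
prediction interval; it reproduces the published table logic rather than a
conventional limits-of-normal band.

## Robust validation statistics

The validation statistics follow the robust trimmed-mean family:

* `bw_trim_anova()` / `bww_trim_anova()`: Johansen-type approximate-df
  tests of contrasts on 20% trimmed cell means with Winsorized covariance
  estimates, for group × condition and group × condition × axis split-plot
  designs. The exact degrees-of-freedom conventions of the cited routines
  are not printed anywhere; the implementation follows the standard
  trimmed-mean/Winsorized-covariance Johansen construction, and its
  acceptance surface is behavioural — simulated type-I error 0.05 ± 0.02
  under normal and heavy-tailed nulls, and agreement with the classical
  split-plot ANOVA when trimming is switched off.
* `winsorized_correlation()`: marginal 20% winsorization, Pearson
  correlation of the winsorized pairs, t test on $n - 2g - 2$ df, and a
  Fisher-z interval using $n$ pairs — the convention that reproduces the
  published intervals for r = 0.52 and r = 0.65 at n = 20 to printed
  precision. Strength labels use the 0.30/0.50/0.70 rule.
* `group_comparison_t()`: pooled t test with Hedges' bias-corrected g.
* `holm_adjust()`: step-down Holm; delegated to `stats::p.adjust`.
* `split_plot_eta_squared()`: generalized eta squared from the classical
  (untrimmed) sums-of-squares decomposition, since trimmed statistics do
  not decompose into sums of squares. It is a companion effect size, an
  approximation consistent with reporting standard ANOVA-summary effect
  sizes alongside robust tests.

## Numerical and design notes

* Coordinates are centimeters in a start-point-centered frame everywhere
  except raw trajectories, which are meters (the robot's native unit);
  conversion happens at time normalization.
* Rejection sampling of shapes is bounded (20 000 attempts per shape) and
  fails naming the violated constraint.
* Degenerate inputs fail explicitly: constant signals (undefined
  correlation), zero-variance paths (degenerate Procrustes), singular
  correlation matrices (naming the most collinear pair), all-invalid
  sessions, zero pooled variance.
* The active-exploration speed draw is truncated just above zero; a
  traversal exceeding the 30 s limit is truncated and flagged, and later
  segmentation flags the missing return instead of failing.
* Problem sizes in the shipped checks are the study sizes where they
  matter (60 healthy, 20 stroke, both conditions; 15 trials; 1 kHz;
  1000-point normalization); oracle comparisons run on small random
  configurations where enumeration is exact, and null-calibration checks
  use 1000–2000 replicates.

## Limitations

The simulator is a single-latent-factor, kinematics-only emulation: no
haptics, arm dynamics, interhemispheric transfer, working-memory decay or
learning effects, and no clinical instrument scores — so convergent
validity against clinical tests can only be exercised on user-supplied
data via `winsorized_correlation()`. Group-level values reported in the
original study (specific F statistics, normative interval endpoints, group
means) depend on the original 80-participant dataset and are not
reproduction targets of the synthetic pipeline; what the package asserts
instead are the analytic fixed points, oracle equivalences, calibration
properties and direction/magnitude of the synthetic group contrast.
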