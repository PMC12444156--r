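---
title: "Kinematic metrics for upper-limb assessment: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematic metrics for upper-limb assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armkin)
```

## The measurement model

`armkin` treats an upper-limb recording as a set of timestamped 3D marker
positions (millimetres, UNIX-epoch seconds) for up to eight landmarks —
left/right wrist, elbow and shoulder, trunk, and an optional neck — with a
per-row *iteration label* that pre-segments the file into movement
repetitions. Segmentation is taken as given: the package deliberately has
no automatic onset detection, because clinical protocols usually define
repetitions explicitly and automatic thresholds are a separate research
question. A maximal run of identical non-rest labels is one segment, with
inclusive boundaries: `t0` and `t1` are the first and last timestamps of
the run, so a segment of `N` samples at rate `fs` has duration
`(N − 1)/fs`.

All per-segment metrics derive from the end-effector path (by default the
wrist of the analysed side) through three stages: numerical
differentiation, a scalar speed profile `v(t) = ||dx/dt||`, and the metric
functionals themselves. Joint-level analysis runs in parallel: per-frame
elbow and shoulder angles, summarised as range of motion over the whole
task — the whole-task window matches how joint mobility is assessed
clinically, while `rom_range()` accepts a segment argument for
per-repetition use.

### Assumptions

* positions are in millimetres and time in seconds — the default
  velocity-peak threshold (δ = 20 mm/s) is only meaningful on that scale;
  a `unit_scale` converts metre-based files on read;
* timestamps are strictly increasing; exact duplicate timestamps are
  collapsed (with a warning) on read;
* marker series are complete — no gap interpolation is attempted, and a
  degenerate frame in an angle computation is an error naming the frame
  rather than a silently imputed value.

## Numerical differentiation

Derivatives use three-point Lagrange stencils on the actual (possibly
non-uniform) time grid: central differences at interior points and
one-sided second-order stencils at the two boundary samples (3 nodes for
the first derivative, 4 for the second). The third derivative — jerk — is
computed as the first derivative of the direct second-derivative estimate
rather than by three repeated first differences. The distinction matters
only at the boundaries, where repeated one-sided first differences
compound their truncation error; with the direct second-derivative route
the integrated squared jerk of a 200 Hz minimum-jerk reach reproduces the
analytic log dimensionless jerk to about 0.003, which the test suite
asserts.

No smoothing or low-pass filtering is applied by default. Differentiation
amplifies marker noise by roughly the sampling rate per order, so noisy
sources (IMUs, low-cost depth sensors) should be filtered *before*
analysis; the synthetic-noise tests show exactly this amplification and
only assert that metric errors vanish as the noise does.

## Smoothness metrics: definitions pinned down

Several smoothness measures are under-specified in common usage; the
package fixes the following conventions.

**Velocity-peak count (NPV).** A single left-to-right scan accepts a
candidate peak iff (1) it is a strict local maximum after collapsing
plateaus to their first sample, (2) it exceeds the most recent preceding
local minimum — or the segment start — by more than δ, and (3) it occurs
at least τ after the last *accepted* peak. A candidate rejected by the
refractory rule does not reset the refractory clock; resetting it would
make the count depend on sub-threshold ripples, which is exactly what the
rule exists to ignore. Defaults δ = 20 mm/s, τ = 150 ms are the
literature-standard values and both are exposed as parameters.

**Acceleration zero-crossings.** The indicator `s̈ᵢ·s̈ᵢ₊₁ < 0` misses
crossings that land exactly on zero, so zero-valued samples are skipped
and signs are compared between nearest non-zero neighbours: a crossing
through zero counts once, a touch-without-crossing counts zero. In the
pipeline the tangential acceleration (first derivative of the speed
profile) is evaluated on interior samples only: at the segment ends the
true acceleration of a rest-to-rest movement is zero, and the one-sided
boundary stencils produce O(h²) values of arbitrary sign there —
counting them would add spurious crossings.

**Log dimensionless jerk.** `LDJ = −ln( (MT⁵/PL²) ∫‖x⃛‖² dt )`, with the
integral by trapezoidal rule. The normalization is fixed by dimensional
analysis — `∫‖x⃛‖²dt` has units mm²·s⁻⁵, so only `MT⁵/PL²` makes the
argument dimensionless — and yields the textbook value `−ln 720` for an
ideal minimum-jerk reach, which anchors the acceptance tests. Jerk is the
third derivative of the 3D position, not of the tangential speed.

**Spectral arc length.** The speed profile (resampled to a uniform grid
if the inter-sample interval jitter exceeds 1% of the median) is
zero-padded to `2^(⌈log₂N⌉+4)` samples and Fourier-transformed; the
magnitude spectrum is normalized by its DC value `V(0)`, truncated at the
cutoff ω_c (default 40π rad/s = 20 Hz, the band of voluntary movement),
and further truncated adaptively at the last frequency where the
normalized magnitude still reaches 0.05; SPARC is the negative arc length
of that curve with frequency normalized to the selected band. This is the
standard published recipe; the unit test cross-checks it against an
independent dense-grid discrete Fourier transform evaluated directly at
20 001 frequencies. The agreement tolerance (0.01) holds for smooth
unimodal profiles; profiles with strong spectral ripple (e.g. widely
separated submovements) have an arc length that legitimately depends on
spectral resolution, so the oracle comparison is only meaningful where
the spectrum is smooth.

## Joint angles

The elbow angle is the angle between the upper-arm vector
(shoulder→elbow) and the forearm vector (elbow→wrist); 0° is fully
extended. No 180° complement is applied — the raw vector angle already
coincides with the clinical flexion angle.

The shoulder angle is measured against a *virtual trunk point*: the
horizontal projection (component along the configured up axis removed) of
the neck→shoulder direction, applied at the shoulder. This mimics
aligning a goniometer's fixed arm with the trunk. The offset magnitude
(default 100 mm) provably cancels from the angle and is retained only for
export and visualisation; the tests assert offset-independence to 1e−9.
Two genuinely open conventions are exposed as arguments rather than
hard-coded: the vertical axis (`up_axis`, default `z` — laboratory
conventions differ) and the sign of the trunk reference direction
(`direction`, default neck→shoulder; the opposite reading is defensible
and flips the angle to its supplement).

When the neck marker is absent it is estimated as the midpoint of the two
shoulders. Any estimator consistent with a level shoulder girdle gives
the same *horizontal* neck→shoulder direction, which is all the shoulder
angle uses, so the midpoint is the simplest adequate choice; it is
applied automatically in `angle_series()` and available explicitly as
`estimate_neck()`.

## The synthetic generator as oracle

`generate_reach()` builds recordings whose kinematics are known
analytically: the wrist follows a minimum-jerk displacement
`x(τ) = D(10τ³−15τ⁴+6τ⁵)` along a straight line; elbow and shoulder
follow by two-link inverse kinematics (upper arm 300 mm, forearm 280 mm —
adult averages; the metrics under test are either invariant to these
lengths or, in the angle sweeps, scripted through them); trunk and neck
are stationary. Movement samples span `[0, T]` inclusively, so the
labelled segment's duration is exactly `T` and the closed forms
(`MV = D/T`, `PV = 1.875 D/T`, `MV/PV = 8/15`, `TPV = 50 %`,
`LDJ = −ln 720`, `NPV = 1`, `HPR = 1`) apply without grid corrections.
Between iterations, rest-labelled rows carry a minimum-jerk return and a
0.2 s pause, so the file exercises the rest-label machinery. The default
conditions — D = 300 mm, T = 1 s, 200 Hz, noise-free, three iterations,
both arms mirrored — are the reference test conditions used throughout
the tests and the acceptance script.

Composed submovements add `k` clamped minimum-jerk displacements at
configurable onsets. Submovements whose onsets are closer than their
duration merge: two unit-duration humps 0.5 s apart sum to a *unimodal*
speed profile, so bimodality fixtures use non-overlapping onsets, and the
smoothness-degradation trials draw onset separations from 1.0–1.3 s with
amplitudes 180–230 mm (keeping the total displacement inside the arm's
workspace, which caps at about 700 mm along the default direction).

Marker noise is isotropic Gaussian, i.i.d. per frame and marker — the
simplest stand-in for optical jitter. What the generator does *not*
emulate: marker dropout and occlusion, soft-tissue artefact, correlated
sensor drift (IMUs), trunk compensation strategies, or genuinely curved
clinical reaches. Passing the oracle suite therefore validates the
*computations*, not robustness to real-world artefacts; noisy or gappy
data need upstream preprocessing.

`generate_angle_sweep()` scripts one joint angle as a raised cosine
between bounds via forward kinematics, giving ROM fixtures with exact
ground truth (recovery within 1° at 100 Hz is asserted).

## Parameters that matter

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `delta` (`peak_params`) | 20 | mm/s | minimum peak prominence over the preceding minimum |
| `tau` (`peak_params`) | 0.150 | s | refractory interval between accepted peaks |
| `omega_c` (`sparc_params`) | 40π | rad/s | spectral cutoff (20 Hz) |
| `pad_level` (`sparc_params`) | 4 | — | FFT zero-padding exponent |
| `amp_threshold` (`sparc_params`) | 0.05 | — | adaptive-cutoff magnitude threshold |
| `offset` (`virtual_trunk_point`) | 100 | mm | trunk-point distance (angle-invariant) |
| `up_axis` | `"z"` | — | vertical axis for the horizontal projection |
| `unit_scale` | 1 | — | input coordinate multiplier (1000 for metres) |
| rest labels | `""`, `"rest"` | — | tokens separating iterations |

## Degenerate inputs and tie-breaks

* `hand_path_ratio` is undefined for closed paths (start = end): error.
* `velocity_ratio` and SPARC are undefined for all-zero profiles: error;
  inside the pipeline such per-segment failures become recorded skips and
  the run continues, since clinical files routinely contain one bad
  repetition.
* Ties at the speed maximum: `time_to_peak_velocity` takes the earliest
  sample, because the metric measures how early the ballistic peak occurs.
* Speed plateaus in peak counting collapse to their first sample.
* Accuracy (target error) and efficiency (hand path ratio) require a
  configured target — they describe goal-directed reaching — and are
  otherwise skipped with a recorded reason, matching datasets that lack
  target annotations.

## Problem sizes

The test suite and acceptance script run on the reference conditions
above: ~1 300-frame recordings (three 201-sample segments), 1 000-point
geometric oracles, 20 randomized degradation trials, and property checks
over dozens of random cases per invariant. The full suite completes in a
few seconds on one CPU.

## Known limitations

* No automatic segmentation, filtering, or gap handling (by design).
* Shoulder and elbow only; no wrist, scapular or inter-joint coordination
  measures, and no endpoint-variability ellipses.
* The shoulder angle collapses 3D arm elevation onto a single
  trunk-referenced angle; pelvic tilt or trunk compensation will leak
  into it, as it does in goniometry.
* SPARC on angular profiles is possible via `scalar_profile` but carries
  no oracle coverage here.
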