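---
title: "Methods: depth-camera behavioral quantification for marmoset stroke models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-camera behavioral quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marmobehav)
```

## Overview

`marmobehav` quantifies the home-cage locomotor behavior of a single
common marmoset from depth-camera recordings, the instrument-based arm of
pre-/post-stroke behavioral studies. The chain is: simulate (or load) a 3D
trajectory sampled at 5 frames/s → render it to depth frames (synthetic
studies only) → track the animal back out of the frames → reduce each
session to daily locomotor metrics → normalize against the animal's own
healthy baseline → bin, test and correlate against the observational
neurological score. Everything downstream of the raw recording is
deterministic given the configuration and seed.

## Geometry and units

The cage frame is right-handed with the origin at the floor corner nearest
the camera: `x` across the image (cage width, 356 mm), `y` along the
camera axis (cage length, 525 mm), `z` vertical (height, 776 mm).
Trajectories are in centimetres, depth maps in millimetres (the sensor's
native unit; 0 encodes an invalid pixel, the usual depth-sensor
convention). The camera is an ideal pinhole 500 mm in front of the cage
face, centred on it; lens distortion and the infrared intensity channel
are out of scope. The default sensor grid is 240 × 320 px with a 150 px
focal length, chosen so the whole cage projects inside the frame with a
few pixels to spare; the constructor rejects intrinsics that crop the
cage.

## The behavior simulator

The generator is a deliberately simple, fully parameterized stand-in for a
caged marmoset; it exists so the tracker and statistics can be validated
against known ground truth, not as a behavioral model of scientific
interest in itself.

* **Rest/locomote switching.** A two-state Markov chain with per-frame
  transition probabilities `p_rest_to_move = 0.02` and
  `p_move_to_rest = 0.05` (at 5 fps: mean rest bout 10 s, mean movement
  bout 4 s, long-run moving fraction ≈ 29%, i.e. ≈ 1.7 h of activity in a
  6 h session). Plausibility choices: absolute activity levels of healthy
  animals are not something the package can calibrate against, so these
  are fixed once and exposed.
* **Locomotion speed.** While locomoting, per-frame speed is drawn from a
  gamma distribution with shape 4 and mean `speed_scale_cm_s` (positive,
  right-skewed, trivially calibrated: the mean *is* the parameter).
  The healthy default is 20 cm/s. That value matters: the metrics layer
  calls a frame "moving" when its speed exceeds 2 cm/s, and for the
  movement threshold to stay negligible the speed scale must remain well
  above it even under the strongest simulated deficit (80% of 20 cm/s
  leaves a 4 cm/s mean, of which ~14% falls below threshold; an 80%
  deficit on a 10 cm/s baseline would truncate more than half of the
  distribution and bias the recovered ratio upward).
* **Heading and vertical wander.** The heading performs a random walk
  (0.6 rad SD per moving frame); a small vertical wander (2 cm/s SD)
  accompanies locomotion so the animal explores the cage height. The
  wander SD is kept small so that its quadrature contribution to 3D speed
  (≈ `sd²/2v`) stays ≪ 5% at the default speed scale, and so it can never
  trip the 120 cm/s jump threshold.
* **Jump/climb events.** A Poisson process (default 2 events/min)
  superimposes a symmetric rise-and-fall triangular vertical excursion of
  0.6 s whose rise and fall rates equal `jump_peak_speed_cm_s`
  (default 150 cm/s). Sampled at 5 fps, a grid-aligned event yields signed
  vertical velocities `{+peak, 0, −peak}` — one upward frame and one
  downward frame — which is exactly what is needed to probe the
  upward-only versus `|vz|` ambiguity in the jump statistic (see below).
  Events start in continuous time, so off-grid events may sample below
  the peak; this attenuates detected counts by a constant factor that
  cancels in baseline ratios.
* **Spatial range.** The animal is confined to `range_fraction` of the
  cage volume (each linear dimension scaled by the cube root, vertical
  range anchored at the floor — an impaired animal stays low), reflected
  elastically at the boundary. Reflection is implemented by folding the
  unconstrained cumulative path, which is equivalent to stepwise specular
  reflection and keeps the generator fully vectorized. All positions are
  additionally inset 4 cm (a body radius) from every wall, since a real
  body centre cannot reach a wall; this also keeps rendered blobs from
  being clipped against wall backgrounds.
* **Deficit and recovery.** A `recovery_schedule` scales four channels
  (speed → `speed_scale_cm_s`, activity → `p_rest_to_move`,
  jump → `jump_rate_per_min`, range → `range_fraction`) by
  `1 − deficit·exp(−(day − onset)/τ)` from `onset_day` on. The deficit is
  maximal at onset and decays monotonically back to baseline. Defaults
  (deficits 0.8/0.8/0.9/0.8, τ = 7 d) reproduce the qualitative published
  pattern: an immediate collapse of all locomotor ratios followed by
  recovery to baseline within two to three weeks. `onset_day = 2` because
  postoperative recording begins on day 2, so the first recorded session
  carries the full deficit.

What the generator does *not* emulate: multi-animal scenes, limb
articulation or fur, feeding and grooming behavior, diurnal rhythm within
a session, sensor-specific artifacts beyond Gaussian depth noise and
uniform dropout. Tests passing on synthetic data therefore demonstrate
correctness of the measurement chain, not performance on real recordings.

## Rendering and tracking

The renderer draws, per frame, the static empty-cage background (exact ray
casts against the cage interior) plus a spheroidal body of radius 40 mm
projected through the intrinsics, then adds zero-mean Gaussian depth noise
and invalidates a `dropout_rate` fraction of pixels.

The tracker mirrors standard depth-video practice:

* **Background**: per-pixel median over reference frames, ignoring
  invalid pixels (from a dedicated empty-cage segment when available,
  otherwise the recording's own frames — the animal occupies any one pixel
  rarely). Pixels invalid in every frame are masked.
* **Segmentation**: foreground = valid pixels nearer than background by
  `delta_mm` (default 40 mm, four noise SDs above the strongest noise
  level considered); connected components at 8-connectivity; the largest
  component is accepted if it has at least `min_blob_px` pixels
  (default 50, about a quarter of the body's projected area at the far
  cage wall under the default intrinsics). Equal-sized largest components
  are resolved toward the nearer blob.
* **Centroid**: the pixel centroid of the blob is back-projected at the
  estimated *body-centre* depth. The mean measured depth over the visible
  near surface of a convex body sits two-thirds of a radius in front of
  its centre (the disk average of the spherical cap), so the centre depth
  is `mean(depth) + (2/3)·r̂` with `r̂` estimated from the blob's pixel
  area. Using per-pixel surface depths directly would both bias the depth
  and shrink lateral coordinates toward the optical axis by the same
  factor.
* **Linking**: a valid detection that jumps more than `max_step_cm`
  (default 60 cm — twice the largest plausible per-frame displacement)
  per intervening frame from the last surviving detection is discarded as
  spurious; then invalid runs of at most `max_gap_frames` (default 5,
  i.e. 1 s) flanked by valid points are filled by linear interpolation.
  Interpolation never extrapolates.

These defaults are validated by the synthetic recovery suite (noiseless:
every frame valid, sub-centimetre RMS error; 10 mm noise with 5% dropout:
RMS well under 2 cm) and are all exposed in the configuration.

## Metrics

Per adjacent valid frame pair: 3D speed over the *actual* timestamp
difference (tolerating frame jitter), signed vertical velocity, and the
moving flag (`speed > 2 cm/s`). "While the animal was moving" has no
standard definition; a threshold separating sensor jitter from locomotion
is the natural reading and the recovered deficit ratios are insensitive to
its exact value in the 1–5 cm/s range provided the speed scale is well
above it. Session metrics: distance (sum of displacements), median moving
speed, activity time (summed moving intervals, also reported as a fraction
of recorded time), jump/climb frames, and a 3D occupancy grid (5 cm cells)
whose fraction of visited cells summarizes trajectory range.

The jump statistic counts *velocity intervals* with vertical speed
strictly above 120 cm/s, upward only, by default. "Advancing vertically"
most plausibly means upward progress (a jump or climb), but since a
symmetric excursion necessarily has matching downward frames, the `|vz|`
reading merely doubles symmetric counts; both are implemented
(`vz_mode = "abs"`), and the strict inequality at the threshold is pinned
by tests at peaks of 119/120/121 cm/s.

## Statistics

* **Baseline ratios**: each postoperative daily value divided by that
  animal's mean over its preoperative sessions; a zero or missing
  baseline (e.g. an animal that never jumped preoperatively) flags the
  ratio missing with a warning rather than failing the run.
* **Binning**: consecutive 3-day windows anchored at postoperative day 1;
  mean and SEM (sample SD / √n; the n−1 convention, since nothing fixes
  the alternative) over all contributing animal-days. Recording resumes
  on day 2, so bin 1–3 holds days 2–3; that asymmetry is accepted as-is.
  Day 0/1 (surgery and first recovery day) are not recorded.
* **Paired tests**: per-animal pairing — each animal's preoperative
  baseline against its postoperative bin mean — which is the defensible
  reading for three animals (pooling animal-days would treat correlated
  days as independent). Identical pre/post give t = 0, p = 1; a constant
  non-zero difference has zero variance and is flagged degenerate instead
  of reported as infinite; under 2 complete pairs is "not computable".
* **Spearman correlation**: midranks for ties, Pearson on the ranks;
  p-value from the t approximation on n − 2 degrees of freedom. The
  default pairing correlates *across-animal daily means* of ratio and
  score (27 postoperative days → n = 27), with per-animal-day pairing
  available. No multiple-testing correction is applied across the four
  metrics, matching how such correlation panels are conventionally
  reported. An all-tied variable leaves the correlation undefined and
  flagged.

## Problem sizes and runtime choices

Simulated studies in the tests and the acceptance script use 10-minute
sessions (3,000 frames) rather than the full 6 h protocol: every estimator
involved (sums, medians over hundreds of moving frames, bin means over
animal-days) is already stable at that size, and a 3-animal, 30-day study
then simulates in seconds. Six-hour sessions are supported
(`session_minutes = 360`) and the renderer/tracker stream frame-by-frame
precisely so that memory stays constant at that scale. Tracker validation
renders 10-minute sessions; the type-I calibration uses 500 replicates of
60 s sessions, enough for the rejection rate's standard error (≈ 0.01) to
resolve the 0.05 target.

## Degenerate inputs and numerical conventions

Trajectories with fewer than two valid points give an empty speed series
(warning, not error); sessions with no moving frame report the median
moving speed as missing; empty bins report n = 0 with a missing mean;
occupancy cells are half-open intervals with points clamped to the cage
grid; depth values are integer millimetres and noisy renders clamp at
1 mm so noise can never silently fabricate invalid pixels. All stochastic
code takes explicit seeds; the pipeline derives per-session seeds from the
master seed so that stages can be re-run independently yet reproducibly,
and the run manifest records md5 checksums of every output.

## On-disk formats

Trajectory, metrics and score tables are plain CSV with fixed headers and
strict validation (monotone time, 0/1 flags, named offending rows). Depth
recordings are directories of 16-bit grayscale TIFF frames (depth in mm)
with a `meta.json` sidecar carrying timestamps and geometry; reads reject
containers whose frame count and timestamps disagree.

## Known limitations

* The tracker assumes a single animal and reports one centroid; occlusion
  by cage furniture, multi-animal housing and identity maintenance are
  out of scope.
* A centroid tracker cannot resolve fine or involuntary distal-limb
  movement, so the observational score retains information the metrics do
  not capture; the correlation analysis quantifies, not replaces, that
  relationship.
* The simulator's deficit channels act independently; real deficits
  couple (an animal that moves less also jumps less), so synthetic
  correlation magnitudes should not be read as predictions for real data.
* Absolute metric values depend on the plausibility defaults above;
  analyses are therefore conducted on within-animal baseline ratios,
  which is also why the package reports ratios rather than raw values.
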