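# marmobehav

Quantitative home-cage behavioral phenotyping for common-marmoset
(*Callithrix jacchus*) stroke models, from depth-camera tracking.

## The problem

Observational neurological scoring of non-human primates is stressful for
the animals, needs trained evaluators, and samples only minutes of behavior
per day. Depth-camera home-cage monitoring instead records the animal's 3D
position continuously (a Kinect-class sensor 50 cm in front of a
525 × 356 × 776 mm cage, 5 frames/s, 6 h/day) and derives daily locomotor
metrics that can stand in for — and be validated against — the clinical
score. `marmobehav` implements that whole analysis chain for people running
or simulating such studies:

* **synthetic data** — a parameterized behavior simulator (rest/locomote
  Markov chain, gamma locomotion speeds, Poisson jump/climb events,
  deficit-with-exponential-recovery schedules) and a depth-frame renderer,
  so the full pipeline runs and is testable with no recordings;
* **tracking** — per-pixel median background model, foreground segmentation
  (8-connected largest blob), back-projection of the blob centroid to cage
  coordinates, spurious-step rejection and gap interpolation;
* **metrics** — per-session distance traveled, median moving speed,
  activity time, jump/climb frames, and 3D occupancy / trajectory range;
* **scoring** — the 4-sign observational neurological score (0–4, one point
  per abnormal sign on the affected side);
* **stats** — baseline-ratio normalization, 3-day binned means ± SEM,
  paired pre/post *t*-tests, and Spearman rank correlation of each metric
  ratio against the score.

## The quantities

For consecutive valid frames at positions \(p_t\) (cm) and times \(t\):

* speed \(v_t = \lVert p_t - p_{t-1} \rVert / \Delta t\); the animal is
  *moving* when \(v_t > 2\) cm/s (configurable);
* distance = \(\sum v_t \Delta t\); activity time = \(\sum_{moving} \Delta t\);
  median moving speed = median of \(v_t\) over moving frames;
* jump/climb frames = #\{t : v^{(z)}_t > 120 cm/s\} (strictly above, upward
  by default; an |v_z| mode is available);
* each postoperative daily value is divided by the animal's mean
  preoperative value (baseline ratio; 1.0 = recovered), binned into 3-day
  windows as mean ± SEM, tested against baseline with a paired *t*-test,
  and correlated with the daily neurological score by Spearman's
  \(r_s\) on across-animal daily means.

## Worked example

Simulate a 3-animal study (3 preoperative days, postoperative days 2–28,
10-minute sessions, deficits on speed/activity/jumping/range recovering
with a 7-day time constant) and run the full analysis:

```r
library(marmobehav)
cfg <- pipeline_config(session_minutes = 10, seed = 7)
res <- run_pipeline(cfg, "demo_out")
print(res$analysis)
```

```
<study_analysis>
  3 animals, preop days {-3, -2, -1}, 3-day bins, alpha 0.05
  binned ratio means (first and last bin per metric):
    activity_time_s            1-3: 0.297 -> 28-30: 1.065
    distance_cm                1-3: 0.126 -> 28-30: 1.029
    jump_climb_frames          1-3: 0.217 -> 28-30: 0.979
    median_moving_speed_cm_s   1-3: 0.286 -> 28-30: 0.986
    range_fraction_visited     1-3: 0.211 -> 28-30: 1.000
  Spearman vs neurological score:
    distance_cm                r_s = -0.855, p = 1.317e-08, n = 27
    median_moving_speed_cm_s   r_s = -0.909, p = 5.31e-11, n = 27
    activity_time_s            r_s = -0.770, p = 2.662e-06, n = 27
    jump_climb_frames          r_s = -0.731, p = 1.478e-05, n = 27
```

Reading this: every locomotor ratio collapses immediately after the stroke
(first 3-day bin far below 1), recovers toward baseline by day 28, and
correlates negatively with the neurological score — more deficit signs,
less movement. `demo_out/` holds per-session trajectory CSVs, the metrics
table, binned series, test and correlation tables, and a `manifest.json`
with checksums; reruns with the same seed are byte-identical.

The tracker can be exercised explicitly:

```r
s   <- simulate_session(behavior_params(seed = 7), duration_s = 600)
tr  <- track_session(s, noise_sd_mm = 10, dropout_rate = 0.05, seed = 8)
attr(tr, "valid_fraction")     # fraction of frames with a detection
```

A thin command-line driver over the same functions is installed at
`system.file("cli/marmobehav.R", package = "marmobehav")` with subcommands
`simulate`, `track`, `metrics`, `score`, `analyze`, `run`.

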