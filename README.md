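# behavtrace

Tracing human behavior from complementary **wearable** and
**premise-embedded** sensors, for home-care and assisted-living
monitoring. Indoors, a camera watches the moving silhouette while a
sternum-worn accelerometer records body motion; the two views are fused
for reliable activity recognition. Outdoors, the wearable network
(accelerometer + GPS, plus ECG) carries on alone. On top of the raw
recognition sits a behavioral layer: pose-state sequences are compared by
dynamic time warping against a library of each subject's safe patterns,
and mismatches are graded normal / suspicious / dangerous / critical by a
database-driven supervision life cycle.

The package implements the full computational chain and ships a
synthetic-data module (scripted scenes, accelerometer/ECG/GPS traces,
synchronized dual streams — all with ground truth), so every stage is
exercisable and testable without real recordings.

## What is inside

**Video features.** Horn–Schunck optical flow on frame pairs $(3n, 3n+3)$
(a 120 ms interval at 25 fps); moving-object masks by thresholding the
flow modulus $|OF|$; the silhouette as the intersection of two consecutive
binarized flows; a ~4 px dilated contour band; and the normalized
direction histogram over eight 45° bins B1–B8 (B1 = motion right,
B5 = motion left). Stacked over time this gives the time–angle matrix of
a movie.

**Wearable processing.** The accelerometer chain — baseline offset
subtraction (10 s stand pose), 0.2 s smoothing, per-subject normalization,
mapping into [0, 1], fourfold decimation to 25 Hz — yielding the
`[x y z]` feature block; fall detection on $|a_x|+|a_y|+|a_z|$ with a
trigger level; Pan–Tompkins QRS detection and heart rate; GPS ground
speed; per-axis MEAN/STD/MIN/MAX summaries.

**Fusion and recognition.** The combined feature vector
`[B1 … B8 X Y Z]`, k-NN classification (k chosen by leave-one-out), the
stratified 10-per-cell learning/testing protocol, per-activity and
per-subject accuracy reports, and a two-feature (acceleration level, GPS
speed) outdoor recognizer.

**Synchronization.** Motion envelopes for both modalities, adaptive
top-5 % salient-section detection over a 15 min history, normalized
cross-correlation delay estimation on a common 100 Hz grid, a 0.7
correlation gate protecting the stored delay, and timestamp compensation.

**Behavior and supervision.** Pose-contribution state vectors over
$P = 7$ elementary poses; DTW with local cost
$d[i,j] = \sum_p (w_{p,1}[i]-w_{p,2}[j])^2$, verified against exhaustive
path enumeration; behavioral-pattern statistics and DTW-based clustering;
the two-level (zones / status) behavioral record; premise and subject
databases; permission checks; N/S/D/C categorization; and the
setup / learning / supervision modes with alerting and review queues.

## Worked example

Render a scripted scene — walk right, stand still, walk left — and read
the motion off the time–angle matrix, then run the fused recognition
protocol on the synthetic benchmark:

```r
library(behavtrace)

scene <- scene_spec(width = 120, height = 70, fps = 25, actor_width = 18,
                    actor_height = 34, background = "constant")
script <- activity_script("V1", data.frame(
  label         = c("6a",  "static", "6b"),
  start         = c(0,      1.8,      3.6),
  duration      = c(1.8,    1.8,      1.8),
  direction_deg = c(0,      0,        180),
  speed         = c(10,     0,        8)))
frames <- render_silhouette_sequence(script, scene, seed = 1)
tam <- time_angle_representation(frames)
round(tam[, c(3, 20, 40)], 2)
#>    [,1] [,2] [,3]
#> B1    1    0    0
#> B2    0    0    0
#> B3    0    0    0
#> B4    0    0    0
#> B5    0    0    1
#> B6    0    0    0
#> B7    0    0    0
#> B8    0    0    0
```

Column 3 falls in the walk-right phase (all mass in B1), column 20 in the
static phase (all-zero histogram), column 40 in the walk-left phase (all
mass in B5) — the time–angle matrix reads the script back.

```r
ds <- synthetic_benchmark(seed = 1)   # 12 activities x 20 subjects
sp <- split_protocol(ds, per_cell = 10, seed = 1)
sp$sizes
#> learning  testing
#>     2400     4874
evaluate(sp$learning, sp$testing, k = 1, mode = "both")
#> <eval_report> mode=both overall=100.0%
#> per activity (%):
#>  1a  1b  2a  2b  3a  3b  4a  4b  5a  5b  6a  6b
#> 100 100 100 100 100 100 100 100 100 100 100 100
```

Ten records per (activity, subject) cell go to the learning set — 2,400
records, leaving 4,874 for testing. On the synthetic benchmark the fused
vector recognizes essentially everything, while the single modalities
(`mode = "video"`, `mode = "acc"`) land in the low 90s: each has a
deliberately ambiguous activity pair that only the other modality
resolves.

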