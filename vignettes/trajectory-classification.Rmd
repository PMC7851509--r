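---
title: "Classifying indoor trajectories for cognitive assessment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying indoor trajectories for cognitive assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(trajcog)
```

## The problem and the pipeline

Dementia-related wandering shows up in how people move at home: pacing
back and forth between two spots, lapping around a fixed circuit, or
meandering without an apparent goal, where a cognitively healthy person
mostly walks directly from one place to another. `trajcog` implements a
pipeline that turns a smart-home position-sensor event stream into a
per-person hypothesis of cognitive status — *cognitively healthy*, *MCI*
(mild cognitive impairment) or *PwD* (person with dementia):

1. **Ingestion** (`load_event_stream`, `to_position_history`): raw firings
   `⟨timestamp, sensor, value⟩` are joined with the sensor position table
   into a position history `H = ⟨r_1, …, r_n⟩`, each record a point in
   home coordinates (meters) at a millisecond timestamp. Only activation
   values (ON/open) witness presence and contribute positions by default;
   a release carries no new position evidence. Door sensors are treated
   exactly like motion sensors, positioned at their mount point.
2. **Cleaning** (`clean_positions`): a reading is deleted when the speed
   from the previous surviving record exceeds `t_v` (default 15 m/s) or
   the step distance exceeds `t_d` (default 5 m; adjacent sensors sit
   within 3 m of each other, so a longer jump cannot be a walked path).
   The scan re-anchors on the survivor after each deletion, which is
   equivalent to re-scanning the whole history after every deletion (the
   suite proves the equivalence against a brute-force oracle).
   Records with zero time difference are collapsed (same position) or
   deleted (different position — an implied infinite speed).
3. **Segmentation** (`segment_trajectories`): a silence longer than `t_s`
   (30–180 s are useful values; 120 s is the default throughout) closes
   the current trajectory. Trajectories are non-overlapping and the next
   one starts at the first record after the gap. The sources describing
   this scheme are ambiguous between that reading and seeding the next
   trajectory with the boundary record; we treat non-overlap as
   definitional (the trajectories partition the history) and expose the
   literal shared-record variant behind `shared_boundary = TRUE`.
   One-record fragments are dropped: a single point has no drawable path
   or speed.
4. **Visual encoding** (`render_traj_image`, `render_speed_image`): every
   trajectory becomes a pair of 100 × 130 px RGB images over a canvas that
   covers the whole home identically for every trajectory (about
   10 px/m on a 10 m × 13 m footprint). The **path-geometry image** draws
   the walked polyline white on black, giving each undirected sensor-pair
   edge a stroke thickness equal to its traversal count (so pacing and
   lapping show as bold strokes), and overdraws every polyline
   self-intersection with a filled red disc of 0.25 m radius (minimum
   1 px) as a marker of path intricacy. The **section-speed image** draws
   each consecutive-record section, 1 px wide, colored by its speed range
   — [0,2) purple, [2,4) violet, [4,6) blue, [6,8) cyan, [8,10) green,
   [10,12) yellow, [12,15) orange, ≥15 m/s red — in temporal order, so on
   re-walked paths the most recent speed wins. Flattening the three
   channels of each pixel row-major and thresholding at zero
   (`flatten_binarize`) yields a binary feature vector of
   3 · 100 · 130 = 39,000 entries per image.
5. **Classification** (`build_two_input_mlp`, `train_model`,
   `predict_trajectory`): a two-branch multilayer perceptron ingests the
   image pair. Each branch is dense-32 (ReLU) → batch-norm → dense-32
   (ReLU) → batch-norm → dropout 0.5; the branches are concatenated into a
   dense layer with three neurons, followed (as specified for this
   architecture, unusual as it is) by batch-norm and dropout before the
   softmax; `head_norm = FALSE` disables those two head layers. Training
   is Adam at learning rate 1e-5 on categorical cross-entropy in
   mini-batches of 64, at most 100 epochs, early-stopped on the loss of a
   stratified 10%-per-class validation hold-out with best-weight
   restoration.
6. **Long-term analysis** (`long_term_diagnosis`): the per-trajectory
   predictions accumulated over the observation window are reduced to the
   most frequent class. Ties break toward the more impaired class and are
   flagged — deterministic and clinically conservative (a false alarm is
   cheaper than a missed decline). Evaluation uses leave-one-person-out
   cross-validation (`lopo_split`, `run_lopo_evaluation`) with
   macro-averaged precision, recall and F1, the right averaging for a
   class-imbalanced cohort.

Two baselines are included for comparison: **numeric features**
(`build_nfe_daily_vector`) — daily Martino–Saltzman pattern counts plus
motion indicators, consumable by any tabular classifier — and the
**binary time-vs-sensor grid** (`render_gvfe_image`), which plots the
k-th firing of sensor ordinal *s* at pixel (k, s); its height always
equals the sensor inventory (67 in the emulated deployment) and its width
is the maximum trajectory length in the corpus.

## Travel patterns and motion indicators

Pattern detection works on the discrete location sequence (the firing
sensors, consecutive repeats collapsed). Scanning left to right,
longest-match-first with pacing preferred on ties, we count
non-overlapping episodes:

* **pacing** — at least three consecutive back-and-forth moves between
  two locations (`A,B,A,B` is minimal);
* **lapping** — at least two complete circular movements over a cycle of
  at least three distinct locations (`A,B,C,A,B,C,A` is minimal; the
  episode is cut at the last complete circuit);
* **random** — a leftover stretch that visits more than four distinct
  locations with at least two direction changes.

The sources leave episode boundaries, overlap and tie-breaking open;
the choices above make the detector deterministic and testable, and the
suite verifies it against exhaustive interval enumeration on *all*
duplicate-free sequences of length ≤ 8 over four locations. Two readings
were genuinely open: "multiple directional changes" is taken as ≥ 2 turns
of at least 45°; and a record consumed by one episode cannot seed
another.

Motion indicators split into kinematics on the raw records — per-segment
speeds, then accelerations and jerks by successive finite differences at
midpoint times, `mean_jerk` the mean absolute jerk (needs ≥ 4 records) —
and geometry on the distinct-position polyline: the angle at an interior
point is the angle between successive direction vectors (straight ahead
0°, U-turn 180°), a **sharp angle** is ≥ 90°, the **turning angle** sums
the absolute angles in degrees, **path efficiency** is start-to-end
distance over walked length, and **straightness** averages the
chord-over-arc ratio `d(p_i, p_{i+2}) / (d(p_i,p_{i+1}) +
d(p_{i+1},p_{i+2}))` over junctions. The straightness wording in the
literature is ambiguous between this bounded reading and its inverse; we
use the chord-over-arc form because it lives in [0, 1] like path
efficiency. A statistic with too few points is reported `NA`, never
coerced to 0.

## Numerical and rasterization choices

* Canvas orientation: origin top-left, y grows downward; width 100 px
  maps home x, height 130 px maps home y. Meters map to pixels by a
  uniform scale `min(W/w_m, H/h_m)` with clamping at the border; the
  inverse map returns pixel centers, so pixel → meters → pixel is the
  identity.
* No anti-aliasing anywhere: binarization at zero would turn any
  anti-aliased halo into spurious features. Lines are Bresenham walks; a
  stroke of width *w* stamps a *w* × *w* square on each line pixel, so
  thickness is monotone in the traversal count. The count is capped at
  7 px to keep heavily paced edges from blobbing out.
* The printed speed-range list skips 14–15 m/s while naming eight colors;
  we close the gap by extending the seventh range to [12, 15), keeping
  the 15 m/s boundary of the red range. Background is black and the path
  white, so that "value > 0" is exactly "something was drawn".
* Intersections are proper crossings between non-adjacent segments
  (T-touches count, endpoint-endpoint closures such as a lap's return do
  not; collinear overlaps have no crossing point); duplicates within
  1 nm are merged. At the default scale the specified 0.25 m disc radius
  is below one pixel, so a 1 px minimum keeps the markers visible.
* The softmax head: the architecture's printed formula embeds a
  `max(0, ·)` inside what its own description calls a standard
  exponential normalization; we implement the standard, numerically
  stabilized softmax over the head's affine outputs.
* Batch normalization uses a running-statistics momentum of 0.9 (faster
  adaptation than the common 0.99, appropriate for the few hundred
  optimizer steps of a desk-scale run); inference always uses running
  statistics and no dropout, so predictions are deterministic and
  batch-size invariant.
* Early-stopping patience is 15 epochs. On a corpus of a few hundred
  trajectories an epoch is only a handful of mini-batches, so a smaller
  patience would stop training before the deliberately low learning rate
  has moved the weights at all; the window is sized in optimizer steps,
  not wall-clock epochs.
* Input weights of features that never occur in a training corpus
  provably receive zero gradient under Adam and stay at their
  initialization; the trainer exploits this to restrict optimizer traffic
  to ever-active features, with bit-identical results.
* Weight initialization is seeded variance-scaled uniform
  (Glorot); all randomness — initialization, shuffling, dropout,
  validation split — flows from the single seed in `train_config`, and
  every simulator stage is seeded, so the whole pipeline is
  bit-reproducible.
* The convolutional baseline (three zero-padded 5 × 5 convolution blocks
  of 32/128/256 filters with 2 × 2 max-pooling, dense 512/128/64, softmax)
  is provided as an architecture constructor with shape arithmetic and an
  eval-mode forward pass; its description elsewhere sets the "pooling
  window size to 22" while also halving the maps, which only a 2 × 2
  window does — we treat the 22 as a typo for 2 × 2. Gradient training in
  this package targets the two-branch MLP, which is the architecture of
  record here.

## What the synthetic cohort emulates — and what it does not

The simulator (`generate_layout`, `simulate_person_day`,
`generate_cohort`) emulates a single-occupant 10 m × 13 m apartment with
51 ceiling PIR motion sensors (a jittered 7 × 7 lattice at ~1.4–1.9 m
spacing plus two hallway sensors) and 16 door sensors — 67 sensors in
all, every nearest-neighbor distance below 3 m. A person-day is a
sequence of 20 trajectories (a session of a few hours), each a
concatenation of 4 travel-pattern episodes; consecutive trajectories are
separated by idle gaps of 200–600 s, so any segmentation threshold up to
180 s recovers the true boundaries exactly. Direct episodes walk
L-shaped lattice routes to one of eight functional anchor locations
(entrance, couch, dining, kitchen, bathroom, three beds) — occupants
walk habitual routes, not arbitrary grid paths — and every generated
episode provably satisfies its own detector predicate (the suite closes
this loop).

Class profiles, fixed as the package's study conditions:

| | direct | pacing | lapping | random | speed (m/s) | pacing moves | lap circuits |
|---|---|---|---|---|---|---|---|
| healthy | 0.92 | 0.03 | 0.03 | 0.02 | 1.10 ± 0.15 | 3 | 2 |
| MCI | 0.55 | 0.35 | 0.05 | 0.05 | 0.85 ± 0.20 | 6 | 2 |
| PwD | 0.25 | 0.10 | 0.35 | 0.30 | 0.60 ± 0.20 | 8 | 4 |

Impairment shifts walking away from direct travel and reshapes its
composition: the MCI profile wanders predominantly by pacing, the PwD
profile by lapping and random meandering, with episode intensity growing
with impairment. This composition difference is what makes the
intermediate class visually separable rather than merely ordinal; the
calibration was piloted once on the default spec and then frozen.

Two noise processes exercise the cleaning and speed machinery.
**Teleport misfires** (3 per 100 events by default) fire a sensor more
than 5 m away 0.1 s after a genuine event; they violate the cleaning
thresholds by construction, and the suite checks ≥ 95% of them are
removed. **Timing jitter** (±0.5 s per firing, order-preserving with a
0.15 s floor) models PIR detection latency and overlapping detection
zones; it spreads apparent speeds well above true walking speed — the
same artifact that populates the upper speed ranges in real PIR
deployments — without ever breaching the cleaning thresholds, so
cleaning remains the identity on noise-free streams. True walking speeds
are realistic indoor values (0.3–1.5 m/s); the upper speed bins are fed
only by apparent-speed artifacts.

What the simulator does **not** emulate: activities of daily living and
their interleaving with locomotion, multi-resident homes, obstacle- or
furniture-constrained paths, sensor dropout, and door-usage semantics
beyond positional firings. Passing the end-to-end recovery check
therefore shows that the pipeline can extract class structure a
clinician would consider plausible from PIR-like data — not that the
classifier would reach the same numbers on a clinical cohort, where the
class signal is far weaker and confounded.

## Problem sizes and what the checks compute

The default evaluation cohort is 30 persons (12 healthy / 10 MCI /
8 PwD), 20 trajectories each, 600 image pairs, leave-one-person-out over
30 folds — sizes chosen so a complete run trains in minutes on one CPU
while keeping every class present in every training fold. On this cohort
the long-term majority vote reaches macro-F1 ≈ 0.96 against ≈ 0.76 for
single-trajectory decisions (seed 1), reproducing the method's central
qualitative claim: aggregation over a person's trajectory history
substantially improves recognition. `scripts/acceptance.R` recomputes
these and the other headline quantities from scratch at any seed.

## Known limitations

* The two-branch MLP on raw binarized pixels needs a few hundred
  trajectories before class-general structure wins over memorization;
  below that, leave-one-person-out performance degrades toward chance
  even when engineered summaries separate the classes.
* Pattern detection depends on the nearest-sensor discretization; in a
  sparser deployment the same walk can read as a different pattern.
* The per-junction jerk estimate is a second difference of noisy speeds
  and is sensitive to timing jitter; it is reported as a baseline
  feature, not a clinical measurement.
* Trained models are tied to the layout transform they were trained
  under; images from a home with a different sensor arrangement are out
  of distribution (no transfer across homes is attempted).
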