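---
title: "Multi-animal tracking with RFID identity assignment: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-animal tracking with RFID identity assignment: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousetrackr)
```

# The problem

Video tracking of group-housed rodents fails in a characteristic way: a
detector produces per-frame bounding boxes without identity, a tracker
strings them into tracks, and every time two animals cross or cluster, the
track identities can silently swap. Without periodic external verification
a single swap propagates through the rest of the recording. `mousetrackr`
implements an offline pipeline that fuses box tracking with RFID reads from
a grid of readers under the arena floor: the tracker preserves short-term
identity through detector failures, and the RFID matcher anchors and
repairs long-term identity, with every decision recorded in a replayable
audit log. A synthetic arena simulator with exact ground truth makes the
whole pipeline testable end to end.

# Tracking model

Each track carries a constant-velocity Kalman filter over the state
$(c_x, c_y, s, r, \dot c_x, \dot c_y, \dot s)$, where $s$ is box area and
$r$ the aspect ratio (held constant); observations are $(c_x, c_y, s, r)$
of the matched detection. Noise covariances are the standard SORT values —
this package modifies the tracker's logic, not its filter tuning. Per
frame, detections are assigned to predicted boxes by maximising total
intersection-over-union (Hungarian algorithm on negated IOU; pairs below
`iou_match_threshold`, default 0.3, stay unmatched; equal-cost ties resolve
to the lowest index, so output is deterministic).

Two behaviours matter for animals:

* **Coasting.** A track that loses its detection emits the Kalman
  prediction (flagged `coasted`) for up to `max_coast_frames` (default one
  second of frames), bridging occlusions and missed detections. Coasting
  requires `coast_min_hits` (default 3) prior matches: a track seen once —
  typically a spurious detection — has no velocity estimate worth
  extrapolating, and letting it coast floods the output with ghost boxes.
* **Re-association.** Sudden turns drop the detection-to-prediction IOU
  below the gate, so a fresh id spawns while the animal's old track coasts
  as a ghost and then goes lost. Three mechanisms recover the identity,
  all deterministic: (i) a *second-chance association* pass re-runs the
  assignment of leftover detections against unmatched tracks anchored on
  their last *observed* box, which does not drift during occlusion;
  (ii) when a track exhausts its coasting budget, a younger track whose
  first box spatially continues the old track's last observed box adopts
  the old identity, and the ghost coasted boxes are deleted
  (*merge-on-loss*); (iii) a detection that appears near a recently lost
  track's final predicted box revives that track (*lost-pool adoption*,
  window `reassoc_window_frames`, default two seconds). The continuation
  test is IOU at `reassoc_iou_threshold` (default 0.3) or, only when the
  scene is unambiguous — a single candidate and no other track within one
  box diagonal — a centroid distance within half the mean box diagonal.
  The ambiguity guard exists because distance-based stitching in a crowded
  cage merges the wrong animals.

Lost tracks keep the box last predicted for them rather than extrapolating
a stale velocity: an animal that disappears into an occlusion re-emerges
near where it vanished, not where its pre-occlusion velocity points.

# RFID identity assignment

Reader zones are user-defined rectangles in image space with a range
radius. A detection is *in range* of a reader when its centroid lies within
the radius of the zone centre **or** its box overlaps the zone rectangle —
the disjunction matters for boxes that straddle a zone edge. Each read is
mapped to the nearest frame by timestamp (reads farther than one nominal
frame interval from any frame are discarded with a warning) and triggers
one of four scenarios:

1. a single in-range track that has **never** been matched: the tag is
   written to the track's whole history, past and future;
2. the track already carries this tag: no-op (a confirmation);
3. more than one track in range: ambiguous, no-op;
4. the track carries a different tag: the assignment is corrected —
   backwards up to the most recent frame where the track was in proximity
   with another track (IOU above `proximity_iou` or centroid distance
   below `proximity_dist_px`; a swap could have happened there) and
   forwards up to the next such proximity event. Later reads repair later
   stretches.

Two refinements extend the same logic, both recorded in the audit log:

* A track that is untagged only *at the read frame* (an earlier bounded
  correction or a uniqueness conflict cleared it) receives a
  proximity-bounded fill rather than a full-history overwrite; overwriting
  a partially confirmed track proved to be the single largest source of
  identity errors in simulation.
* After all reads are processed, a bridging pass fills unassigned runs
  within each track: interior runs flanked by the *same* confirmed tag
  inherit it; edge runs extend the adjacent tag to the track ends; where
  the flanks disagree, a swap must have occurred at a proximity event
  inside the run, so the left tag is filled up to the run's first
  proximity event and the right tag from its last one — only the stretch
  in between remains unassigned.

On every frame a tag labels at most one track; a conflicting holder is
reverted to unassigned and the event logged. Replaying the audit log from
an empty table reproduces the final assignment exactly
(`replay_audit()`), which the test suite asserts.

In home-cage mode a designated entrance reader participates normally, but
reads from the other (cage) readers are suppressed while the in-range
track sits within `entrance_stop_distance_px` of the entrance zone,
because animals entering or leaving the housing area appear and disappear
there; the stop distance has no canonical value and must be configured.

# Motion detector

Frames are smoothed with a 21×21 Gaussian kernel; the background is an
accumulated running average ($B \leftarrow (1-\alpha)B + \alpha\,x$,
$\alpha$ = 0.05); pixels whose absolute difference from the background
exceeds `diff_threshold` (25 on an 8-bit scale) are foreground, and
connected components of at least `min_contour_area` pixels flag the frame
as containing motion. The first second of frames only builds background
and is never flagged. Active duration sums the inter-frame intervals of
flagged frames; the final frame contributes the nominal interval, so $n$
flagged frames at a constant rate $f$ sum to $n/f$ seconds (the same
convention is used for centre occupancy and interaction durations).
Smoothing and component labelling use EBImage.

# Trajectory and social metrics

* **Simplification.** Ramer–Douglas–Peucker with tolerance ε = 10 px by
  default; turn angles are computed on the simplified path because raw
  centroid jitter manufactures spurious sharp turns.
* **Turn angles.** The angle between successive displacement vectors, in
  [0°, 180°]; straight continuations (angle ≈ 0) are not turning events.
  Events split into sharp (below the threshold) and wide (at or above it);
  an angle exactly at the threshold counts as wide, since the field's
  "<90°"/">90°" convention leaves equality unclassified. The default
  threshold is 90°, with 45° the documented alternative for fine motor
  assessment.
* **Centre occupancy.** The centre is the axis-aligned rectangle of half
  the arena width and height, centred; occupancy sums per-sample
  durations.
* **Interaction (ITC) episodes.** Two animals interact on a frame when
  their boxes, each enlarged to 125% of its area (sides scaled by
  $\sqrt{1.25}$, centre preserved), overlap. Maximal runs of interaction
  frames are episodes; totals, counts and mean durations are reported per
  pair and per animal.
* **Track-pattern difference.** Trajectories of a two-animal trial are cut
  into contemporaneous 5-s windows (shared grid; trailing fragments
  dropped). A window pair is scored only if both segments have start–end
  displacement above 1 cm and path lengths within 35% of each other.
  Coordinates are z-normalised per axis (sample standard deviation;
  zero-variance axes map to zero) and compared by dynamic time warping
  over the full alignment lattice with squared-Euclidean local cost; the
  score is the square root of the optimal accumulated cost, hence 0 for
  identical shapes and invariant to translation and uniform scaling.
* **Spatial proximity (SP).** The symmetrised mean of minimal
  point-to-trajectory distances on *raw* pixel coordinates. Pairs with
  SP at or below `sp_split` (default 300 px, meaningful at roughly
  960×960 px arena resolution and in need of recalibration at others) are
  *proximal*, the rest *distal*; equality is proximal.

# Evaluation

Hypothesis boxes (coasted ones included — they are first-class outputs)
are paired with ground-truth boxes frame by frame by best-IOU one-to-one
matching at IOU ≥ 0.5. From the pairing: false negatives (ground-truth
animals missed), false positives (boxes with no animal), identity errors
(paired boxes whose tag disagrees with truth), and

$$\mathrm{MOTA} = 1 - \frac{\sum_f \mathrm{FN}(f) + \mathrm{FP}(f) +
\mathrm{IDerr}(f)}{\sum_f \mathrm{GT}(f)},$$

which is 1 exactly when all three error sums are zero and is not floored
below zero. Coverage is the percentage of tracked boxes carrying a tag;
the identity error rate is the percentage of tagged boxes whose tag
disagrees with the overlapped ground-truth animal. Ground truth comes from
the simulator for automated tests, or from a human-annotation CSV in the
same schema (`frame, tag, x_min, y_min, x_max, y_max`) for real videos.

# The synthetic arena

`simulate_session()` generates the full session file set with ground
truth. What it emulates, and the defaults it fixes:

* **Geometry.** Three presets mirror common recording setups: a modified
  shoebox home-cage (29 × 19 cm, six readers in a 3 × 2 grid, 512 × 400 px),
  a 32 × 32 cm open field (nine readers), and a three-chamber arena
  (60 × 20 cm, four readers). Reader spacing is validated against a
  configured minimum (12 cm where the geometry allows it; 9 cm under the
  compact home-cage, where a six-reader grid cannot be spaced wider).
* **Movement.** A correlated random walk: per-frame heading perturbation
  with standard deviation $(1-\text{persistence})\pi$ (persistence 0.85),
  truncated-Gaussian speed (mean 8, sd 4 cm/s), gated by a two-state
  move/rest Markov bout structure (mean active bout 8 s, rest bout 12 s,
  hence ~40% activity and an overall mean speed near 2 m/min — home-cage
  locomotion is intermittent, not continuous). Walls reflect specularly.
  Mice are solid bodies: a soft repulsion keeps centroids at least 3 cm
  (about one body width) apart, so boxes overlap during contact but never
  coincide — coincident boxes are physically impossible and would make
  box-only assignment arbitrary.
* **Detector noise** (the `noisy` preset): Bernoulli dropout
  (p = 0.02 per detection), corner jitter (sd 1.5 px), spurious boxes
  (Poisson, 10/min), and occlusion merging — when two true boxes exceed
  IOU 0.15 they form a contact episode, and with probability 0.5 *per
  episode* the detector reports a single union box for the whole episode.
  The draw is per episode, not per frame: real detectors fail persistently
  while the geometry persists rather than flickering between one and two
  boxes.
* **RFID reads.** Bernoulli per frame (p = 0.1; 1.0 in the clean preset)
  for each mouse within a 6 cm read radius, with a 1 s per-reader
  refractory interval emulating polling; among simultaneous candidates one
  tag is read. The session config declares reader range radii 10% larger
  than the physical read radius so that every position that can emit a
  read lies inside the matcher's range test.
* **Reproducibility.** All randomness flows from the single seed passed to
  `simulate_session()`; the same seed reproduces the session byte for
  byte.

What the simulator deliberately does **not** capture: posture and body
deformation (animals are rigid boxes), appearance (no basis for visual
re-identification, which the pipeline does not use anyway), correlated
detector failures other than occlusion merging, bedding-dependent RFID
attenuation, and multi-animal read collisions beyond the one-read-per-poll
rule. Passing the simulation floors therefore demonstrates that the
tracking and matching logic is sound under realistic detection and read
statistics; it does not certify performance on any particular real video.

# Numerical choices and degenerate inputs

Equal-cost assignment ties go to the lowest index; re-association ties to
the most recently lost (or most recently born) candidate. Degenerate
(zero-area) boxes are errors at the geometry layer; the Kalman filter
clamps predicted area at a small positive floor. Zero-variance axes in
z-normalisation map to zeros; zero-length steps are skipped in turn-angle
computation; zero time-steps are dropped (and logged) in kinematics. A
session with no ground-truth animals has undefined MOTA and is an error.
An SP exactly at the proximal/distal split counts as proximal; a turn
angle exactly at the sharp/wide threshold counts as wide.

The automated checks run 10-minute sessions at 15 fps (9 000 frames): one
clean single-animal session, and three seeds of the four-animal noisy
preset for the coverage (≥ 88%) and identity-accuracy (≥ 85%) floors —
sizes chosen to match the validation recordings the pipeline is aimed at
while keeping a full suite run within a coffee break.

# Known limitations

* Identity through a long occlusion is decided by RFID reads, not vision;
  a cage region far from all readers can harbour long unassigned or
  (rarely) misassigned stretches until the animal next crosses a reader.
* Scenario-3 (ambiguous) reads are discarded entirely; in dense groups a
  substantial fraction of reads carries no information.
* The correction boundary treats *any* proximity event as a potential
  swap; in practice most proximity events swap nothing, so corrections are
  more conservative than strictly necessary.
* The motion detector has no illumination-change or shadow model; abrupt
  global lighting shifts will flag motion until the background re-adapts.
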