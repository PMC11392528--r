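---
title: "Methods: visual-field reconstruction and escape contagion in foraging flocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visual-field reconstruction and escape contagion in foraging flocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flockgaze)
```

This vignette documents the models, rules and numerical choices behind
`flockgaze`, in the spirit of a statistical-methods section: what is
computed, under which assumptions, which constants matter, and what the
synthetic-data tests do and do not establish about real recordings.

## The head-local frame and foveal projection

Birds move their gaze mostly with their heads. We therefore reconstruct a
rigid *head frame* per video frame and treat gaze analysis as geometry in
that frame. The frame is anchored in a one-off per-bird calibration: the two
eye centers and the beak tip, expressed in the same coordinate system as a
rigid template of four head markers.

- The origin is the head centroid, the midpoint of the eyes.
- X points from the left eye to the right eye.
- Y (forward) is the beak principal axis (centroid to beak tip,
  orthogonalized against X) rotated upward about X by 30°. This places the
  *local horizon* 30° above the beak axis, matching the typical standing
  posture of a pigeon; with the head held naturally, the local XY plane is
  approximately horizontal. The offset is a fixed constant, not fitted per
  trial; its across-individual variation is small relative to the 10° foveal
  margin.
- Z = X x Y completes a proper right-handed rotation.

Per frame, the calibration template is registered to the observed head
markers by least-squares rigid fit (orthogonal Procrustes via SVD, reflection
guarded). All visible markers are weighted equally; frames with fewer than
three markers are *missing*, not errors, because dropouts are routine in
motion capture. The fit degrades gracefully: three exact markers still
determine the pose.

A world point projects to egocentric *azimuth* (signed angle of the
horizontal-plane projection from +Y, positive to the bird's right, range
(-180, 180]) and *elevation* (angle above the local XY plane, [-90, 90]).
The sign convention (positive azimuth = right) is a package choice; the
right-handed frame with X = right makes it the natural one.

The pigeon fovea projects laterally at ±75° azimuth, 0° elevation. An object
is *foveated* when its center falls within a rectangle of ±10° in both
azimuth and elevation around a foveal axis. Two choices here are deliberate:

- **Rectangle, not cone.** The foveal region is rectangular in
  (azimuth, elevation) space, matching how visual-field heatmaps are
  aggregated in 5° cells; `offset_from_fovea()` provides the great-circle
  distance for diagnostics. Near 0° elevation the two differ by at most a
  few percent of area.
- **Either eye counts.** Results are not separated by eye; a foveation on
  an object is scored if either eye's region contains it.
- **Center-only inclusion.** Scene objects are spheres, but the inclusion
  test uses the projected sphere *center*. An angular-radius overlap test
  would make distant small objects and near large ones behave differently in
  ways the margin already absorbs; the margin (±10°) is itself the
  documented allowance for uncompensated eye movements (≤ 5° in pigeons).

## Preprocessing at 60 Hz

Raw marker trajectories are gap-filled (linear interpolation of positions,
spherical-linear interpolation of orientations) across gaps up to 0.2 s;
longer gaps stay missing. Single-frame "teleports" (both adjacent steps
above 20 m/s or 3000°/s) are masked as tracking spikes. Smoothing is a
zero-phase moving average over 0.1 s (positions componentwise; orientation
matrices averaged and projected back to SO(3)), with window shrinkage at
boundaries. These are deliberately simple, fully specified filters standing
in for the external filtering pipeline used with the original recordings;
every constant is exposed in `run_config()` / function arguments.

One consequence matters for event timing: a centered 0.1 s window smears a
saccade offset by roughly half a window (2–3 frames). On noisy data this is
the right trade — smoothing is what makes foveation tracking reliable at
realistic marker noise; on noise-free data it is pure distortion. The
zero-noise recovery tests therefore run with `smooth_window_s = NULL`, which
is also why they can demand foveation-latency recovery to within one frame
(1/60 s).

**Head saccades** are maximal runs of frames with geodesic angular speed
above 60°/s that last at least 50 ms and whose *net* rotation (start to end
of the run, not path length) exceeds 5°. Net displacement is the reading we
adopt for "movement larger than 5°"; a cumulative-path variant would count
slow tremor. Fixations are the complementary intervals. Saccade frames are
excluded from all foveation data, on the assumption that visual processing
is suppressed during rapid head rotation.

## The posture ethogram

Per-frame labels come from fixed thresholds on 3D posture:

| behavior | rule (constants as defaults) |
|---|---|
| head-down | head centroid strictly below the body centroid (back-cluster centroid − 6 cm) |
| peck (event) | beak tip < 4 cm above the ground with pitch > −100°; event at the beak-height minimum of each dip |
| feeding | any time between consecutive pecks ≤ 6 s apart |
| grooming | back-preen: head-direction vs body→head angle > 60° and beak within 10 cm of the body center (or > 40° with the head above the body); breast-preen: pitch < −100°, or < −80° with angle > 60°; scratch: \|roll\| > 50° with the head < 3 cm above the body |
| courting | ≥ 2 bows in any 8 s window, within 0.6 m of a neighbor and oriented toward it within 120°; episodes < 1 s dropped; the target is "courted" |
| running away | speed > 0.6 m/s while the distance to the active monitor grows at > 0.2 m/s, not courting/courted; runs < 70 ms dropped |
| flying | speed > 2 m/s for ≥ 70 ms |
| head-up | residual valid frames |

*Pitch* is the elevation of the forward axis, extended past ±90° using the
dorsal axis (an upside-tilted head has |pitch| > 90°), so "pitch < −100°"
is well defined for breast preening. A *bow* is a pitch dip of ≥ 25° below
the bird's rolling-median pitch (8 s window) that returns within 2 s — the
bow amplitude is a package constant, chosen well above pecking-dip
amplitudes and well below preening pitches. Radial speed uses a 0.25 s
centered difference for robustness at 60 Hz; body speed a one-frame centered
difference.

Co-firing rules are resolved by precedence **flying > running away >
courting > grooming > feeding > head-down > head-up**. Locomotor escape
dominates so that escape latencies are never masked by, say, a feeding label
(the feeding rule spans whole inter-peck intervals and would otherwise
swallow short runs). The "courted" flag uses the courting bird's orientation
cone only, not mutual orientation.

## Gaze events, latencies and heatmaps

Foveation events are maximal runs of foveated frames *after* saccade-frame
removal; runs shorter than 300 ms are dropped (the typical inter-saccadic
interval; shorter crossings are likely incidental). The minimum is applied
after removal, so a saccade splitting a long foveation leaves two events
that are re-measured individually.

The **latency to foveate** on the predator cue (the active monitor or its
hiding table) is the start of the first qualifying foveation after looming
onset, with two exclusions: events starting in the first 200 ms do not
qualify (the gaze was plausibly already crossing the cue; pigeon reaction
times exceed 200 ms), and if the first qualifying foveation begins only
after looming offset the case is returned as missing and excluded from
latency analyses. Run and fly latencies are the onsets of the first
running-away / flying intervals after looming onset;
*escape-before-offset* flags either onset occurring within the looming
period.

Visual-field heatmaps bin object-center angles into 5° × 5° cells over the
full sphere of directions (72 × 36, left-closed bins from −180° and −90°;
the 180°/90° boundary folds into the top cell), normalized to unit sum. The
sampling window runs from looming onset to the first escape response (run
*or* fly, whichever is earlier) or looming offset. The foveal-region
frequency sums the cells inside the two 75 ± 10° / 0 ± 10° rectangles and is
logit-transformed after clipping to [1e-4, 1 − 1e-4].

Before-cue metrics summarize the 120 s before looming onset: proportion of
valid frames head-up, peck and saccade rates (per second of window), and
proportions of frames foveating any monitor / any conspecific.

## The escape-contagion permutation test

The question: within a predator presentation event, are the birds' escape
latencies more clustered in time than expected if birds responded
independently? The statistic is the mean *time gap* — the mean successive
difference of the sorted latencies (equivalently, range / (n − 1)).

Matched pairs are formed from events sharing the trial round and the
presentation side but coming from the two different flocks; with the full
design this yields 12 pairs. Within a pair, the pooled latencies are
reassigned to the two events uniformly at random (group sizes preserved)
10,000 times; the p-value is the proportion of permuted mean gaps less than
or equal to the observed one. Choices worth stating:

- **Ties count as extreme** (≤, not <): conservative.
- **Raw proportion**, no +1 smoothing, matching the proportion-based
  definition; a smoothed variant is available by flag.
- **Aggregation**: permutations run independently per pair; per
  permutation, gaps are pooled over pairs weighted by gap count (total
  summed gap / total gap count). The observed statistic is computed
  identically.
- **Non-responders** are simply absent from an event's latency set; pairs
  left with fewer than two responders per event are dropped and counted.
- **Distance control**: each pair can first be restricted to the
  individuals whose distance to the active monitor lies in the overlap of
  the two flocks' [min, max] distance ranges (inclusive); an empty overlap
  drops the pair. This guards against purely spatial clustering masquerading
  as social contagion.

Under the independent-latency generator, the aggregate test's type-I error
at the 5% level, estimated from 500 replicate full designs at 1,000
permutations, falls within 0.05 ± 0.02 (`scripts/acceptance.R` recomputes
this). Power under the default coupling is essentially 1, and mean p-values
decrease monotonically with coupling strength.

## What the synthetic flock emulates — and what it does not

The generator replays the experiment's structure with complete ground truth:
a 15 × 7 m room with monitor + hiding-table assemblies at two opposite
corners; 20 birds in 6 rounds, each split into two flocks of 10 under the
constraint that every pair of birds shares a flock at least once (randomized
search with targeted repair of never-paired birds, who are exactly those
with complementary flock-membership vectors); two events per session with
counterbalanced sides; 60 Hz kinematics.

Per bird it scripts: a heading-random-walk foraging path (~0.1 m/s) on the
central feeding area; feeding bouts (pecking dips that take the beak below
4 cm, ~20° pitch dips so that pecks are not mistakable for courtship bows);
head-up scanning with fixations (0.3–0.8 s) and saccades (10–60° at
100–500°/s), with occasional deliberate monitor checks; grooming bouts
(breast-preen pitch, never chained back-to-back, since a truncated entry dip
would mimic a bow); and for each event a lognormal detection latency
(median 3 s, capped at 12 s → non-detector), after which the gaze saccades
to and *tracks* the active monitor in the foveal region, a run onset
(detection + lognormal delay, ≥ 1 s), and a flight onset from the contagion
model: each bird's independent flight time is detection plus a lognormal
delay (median 8 s), and with coupling c > 0 every bird after the first flyer
flies at the first flight time plus an Exp(0.3/c s) delay, truncated at its
own independent draw. Escape bursts move straight away from the monitor
(1 m/s runs, 3 m/s flights) and end early if the bird reaches the room
margin ("landing"). Marker output applies the head/back templates (3 cm
tetrahedral head cluster; 7 × 3.5 cm back plate) to the scripted poses plus
isotropic noise (1 mm default), with noise drawn from a detached RNG
substream so ground truth is byte-identical with or without marker emission.
The looming stimulus exists only as event timestamps.

Not emulated: eye-in-head movement (folded into the ±10° margin), marker
occlusion patterns of real self-grooming (real head-data loss was ~10% per
trial; the generator's default dropout is zero and is a parameter),
biomechanically realistic flight arcs, marker identity swaps, and any visual
rendering. Passing the recovery tests therefore shows that the *pipeline
logic* is faithful — rules recover what the rules define on clean
kinematics — not that the thresholds are optimal for any particular real
arena.

Sensitivity to marker noise is dominated by the head-cluster size: with a
3 cm cluster, 1 mm of isotropic marker noise leaves a few degrees of
per-frame orientation error (smoothing reduces it; detection recall stays
complete in the test suite's checks), while 5 mm leaves errors of the same
order as the 10° foveal margin, and foveation tracking degrades badly. Real
deployments with comparable cluster sizes should expect the same scaling.

## Numerical choices and degenerate inputs

- Rotations are averaged componentwise and projected to SO(3) by SVD (sign
  guarded); slerp goes through axis–angle with a stable near-180° branch.
- Tie-breaks: peck events take the earliest beak-height minimum; heatmap
  boundary angles fall into the higher bin.
- Degenerate calibrations (coincident eyes, collinear beak, collinear
  template) raise errors at construction; per-frame failures (< 3 markers)
  are masked frames.
- A permutation test on identical pooled latencies is degenerate and
  returns p = 1 with a warning.
- All generator randomness flows from one seed via fixed per-session
  offsets; identical seeds give byte-identical marker tables.

## Problem sizes in tests

The test and acceptance runs use scaled sessions — free-feeding periods of
12–35 s instead of 2–5 min, and one to twelve sessions depending on the
check — chosen so that the whole suite exercises every stage (including
500 + 200 replicate permutation designs and a ~200-observation latency-model
recovery) in a few minutes. Event structure, rates and all thresholds are
the defaults throughout; only durations and session counts are scaled.

## Known limitations

- The ethogram can label pecking toward a close frontal neighbor as
  courtship when dips are deep enough to qualify as bows; the rule set has
  no feeding-vs-courting disambiguation beyond precedence.
- Running detection is referenced to a designated active monitor; outside
  predator events the label is not meaningful.
- The heatmap's "before any escape response" truncation uses whichever of
  run or fly comes first; variants differ only for birds that run long
  before flying.
- The distance-overlap control filters by marginal range overlap only; it
  does not reweight within the overlap.
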