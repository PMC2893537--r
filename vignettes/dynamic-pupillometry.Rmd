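---
title: "Dynamic pupillometry with plrkit: models, detection and parameter extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic pupillometry with plrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plrkit)
```

## The measurement problem

Dynamic pupillometry records the pupil's response to brief light flashes
with an infrared camera and reduces each recording to a small set of
physiologically meaningful numbers: how large the pupil is in darkness
relative to the iris, how quickly and how far it constricts after a
flash, and how it recovers. Because the parasympathetic pathway drives
constriction and the sympathetic pathway drives redilation, these
parameters are used to screen for autonomic dysfunction — in
particular in diabetes, where pupillary abnormalities can precede
cardiovascular autonomic neuropathy (CAN).

`plrkit` implements the complete offline analysis chain for such
recordings: per-frame pupil and iris radius measurement from grayscale
eye images, pupillogram (radius versus time) construction, extraction
of the single-flash and 25-flash parameter sets, and the three-group
comparison statistics. Since no public recordings accompany the method,
the package also contains a first-class synthetic generator — an
analytic reflex model plus an eye-image renderer — whose ground truth
is known exactly, so every downstream stage is testable end to end.

## The generative reflex model

`plr_model()` describes one subject's reflex with seven parameters:

* `baseline_radius_px` — dark-adapted pupil radius (default 60 px on a
  110 px iris, a pupil/iris ratio of 0.55 typical of healthy eyes);
* `min_radius_px` — radius at maximal constriction (default 42 px, a
  30% constriction);
* `latency_onset_s`, `time_to_min_s` — delay before constriction
  starts and time from flash to the minimum (defaults 0.2 s and 0.9 s,
  in line with published healthy-group latencies);
* `recovery_plateau_fraction`, `recovery_tau_s` — the exponential
  redilation recovers toward `fraction * baseline` (defaults 0.85 and
  1.2 s);
* `train_adaptation_fraction` — under 1 Hz flash trains the effective
  pre-flash baseline shrinks geometrically, `B_k = aB + (1-a)B a^(k-1)`,
  converging at rate `a` to the fraction `a` of the dark baseline
  (default 0.6, which reproduces the observed drop of the pre-flash
  pupil/iris ratio from ~0.55 in darkness to ~0.33 mid-train).

The single-flash curve is piecewise analytic — baseline hold, linear
constriction, exponential recovery — so every measured parameter
(the 90%-of-baseline onset crossing, the minimum and its latency, the
75%-of-baseline plateau crossing) has a closed form, returned by
`plr_truth()`. Within a 1 Hz train the constriction phase is capped at
0.68 s (the latency-to-largest-constriction observed under repeated
flashes) and the recovery rises to the next flash's adapted baseline,
holding it over the last 50 ms of the window, so the frame preceding
each flash sits exactly at `B_k` for any frame rate of at least 20 fps.
The final (25th) window reverts to the single-flash shape so the
recovery plateau exists.

These piecewise-linear segments are a deliberate simplification: real
pupillograms have smooth sigmoid constriction, hippus, and
measurement noise correlated in time. The model's purpose is exact
recoverability, not physiological realism; what passing tests show is
that the measurement chain is unbiased and correctly wired, not that it
has been validated against human recordings.

## The rendered scene

`eye_scene()` emulates the recorder's IR view: a dark pupil disk at
gray level 35 (the level the original system observed under its fixed
illumination), an iris annulus (default gray 160, radius 110 px) on the
dark interior of the stimulator cone, four near-saturated glints from
the IR LEDs placed symmetrically around the pupil center, an optional
eyelid occluder covering a stated fraction of the pupil circumference
from the top, and optional additive Gaussian gray noise. Disks are
anti-aliased by fractional pixel coverage, so the rendered pupil area
tracks pi r^2 within a perimeter-wide band. Blink frames are rendered
fully occluded at the eyelid (iris-like) gray level — the simplest
signal for blink handling.

No published image dimensions exist for the original recorder; the
default 240 x 320 frame with an integer pupil center is this package's
choice (radius, not center, is the measurand). Iris texture, corneal
refraction and gaze are out of scope.

## Per-frame detection

`measure_frame()` runs the published three-step algorithm:

1. **Glint elimination.** A Canny detector with high threshold 0.8 (on
   gradient magnitude normalized to its maximum) returns one-pixel
   contours around the high-contrast reflections; contours are filled
   by flood-filling the background from the border (closing
   border-touching contours against the border first) and the filled
   regions are replaced by gray 35. Two safeguards are ours: filled
   regions must contain a near-saturated pixel (default >= 200) to
   count as reflections — otherwise a glint-free frame would lose its
   iris — and the fill mask is dilated 2 px to cover the anti-aliased
   halo.
2. **Edge enhancement.** High-boost sharpening `A*I - blur3x3(I)`
   (A = 2 by default; the original publication names the filter family
   but not the kernel) followed by the 0.6-gamma intensity
   transformation, which stretches contrast at the dark end where the
   pupil-iris frontier lives.
3. **Edge detection and circle fitting.** Canny with threshold 0.5
   marks the pupil-iris frontier; the radius is then found by
   correlating the edge map with zero-mean anti-aliased annular
   templates over radii 20-90 px in 0.2 px steps and integer centers,
   reporting the maximum normalized correlation. Ties break toward the
   smaller radius. The center search is staged — an exhaustive window
   around the edge centroid, expanded while the optimum sits on the
   window hull, with a coarse re-seeding sweep if the score stays below
   the convergence floor (heavy occlusion shifts the centroid) — and
   agrees with brute force over every integer center, a property the
   test suite asserts against an independently coded exhaustive oracle.
   A fit scoring below ~25% of an ideal ring's correlation (floor 0.2)
   is flagged unconverged; that flag is the blink signal.

The published description leaves several constants open; our
conventions (all configurable in `detect_config()`): hysteresis low
threshold = 0.4 x high, Gaussian pre-smoothing sigma = 1 px, ring
template thickness 1 px. The iris is located once per recording by a
circular Hough transform over radii 95-140 px with circumference-
normalized votes and parabolic sub-bin refinement, and reused as the
ratio denominator (the published ratios are per-recording).

Numerically, the template correlation is computed exactly from sorted
pixel-center distances and prefix sums (three radial sums per
candidate), with the all-pixel template norms cached per radius grid
for centers whose ring support lies inside the image — this is what
makes the 0.2 px grid affordable at video scale (about 0.1 s per frame
on one core).

## Pupillogram and parameters

`build_trace()` assembles radius versus time; invalid frames stay as
gaps and are never interpolated (a blink could fake a minimum).
Crossings interpolate linearly between adjacent valid frames (sub-frame
resolution); minima are frame-aligned, matching the frame-based values
the method reports. Blinks are maximal runs of invalid frames, plus
frames jumping more than 10 px/frame; recordings with more than three
blinks are excluded — `extract_single_flash()` and
`extract_flash_train()` refuse them.

Two printed quantities are ambiguous in the source description and are
therefore configuration, not guesses (`extract_config()`):

* **Duration of constriction** is labeled but never defined, and the
  published group means (~1.6 s) exceed the latency-to-minimum
  (~0.9 s), so it cannot be onset-to-minimum. Default: onset crossing
  to the first sustained redilation (three consecutive rising valid
  frames at or after the minimum); onset-to-minimum and
  onset-to-75%-recovery are selectable.
* **Velocity of constriction** follows the literal definition,
  amplitude divided by the duration of constriction, by default; the
  published velocity means are more consistent with an
  onset-to-minimum denominator, available as an option. Either way
  `velocity x denominator = amplitude` holds identically for every
  extracted record.

The plateau radius is taken at the 75% upward crossing itself (the
alternative — a later steady value — is not what the parameter list
says). The single-flash minimum is searched within 1.5 s after the
flash; train minima within each flash's own 1 s window.

## Cohort simulation and statistics

`generate_synthetic_cohort()` samples per-subject models from
group-level distributions whose pupil/iris ratio and latency means/SDs
follow the published three-group comparison (healthy 0.55 +/- 0.056,
diabetic without CAN 0.42 +/- 0.045, with CAN 0.35 +/- 0.077; n =
16/16/8). Draws are truncated to valid ranges; the constriction
fraction gets a small SD (0.02) and a 0.74 ceiling so the 75% plateau
exists for essentially every subject. `cohort_parameters()` pushes each
subject through the analytic trace and the extraction stage — no
rendering, so a 40-subject cohort takes well under a second.

`build_results_table()` mirrors the published table structure: mean and
sample SD (n-1) per group; one-way ANOVA with Bonferroni post-hoc for
the two healthy-versus-diabetic contrasts (p1, p2); Kruskal-Wallis for
the diabetic-versus-diabetic contrast (p3); significance at 0.05 with
the */#/$ notation. The tests are base R's `oneway.test`,
`pairwise.t.test` (pooled SD — the classical post-hoc; whether the
original analysis pooled variances is unstated) and `kruskal.test`;
the test suite checks both against explicit sum-of-squares and
rank-sum oracles. No correction is applied across parameters, matching
the original analysis. Note the synthetic cohort's pixel-valued
parameters (e.g. amplitude) are on this package's 110 px-iris geometry,
deliberately not the original camera's scale; ratios and latencies are
scale-free.

## Problem sizes and determinism

The shipped tests and the acceptance script work at the study's own
scales: 90-frame (3 s) single-flash and 900-frame (30 s) train videos
at 240 x 320, a 15-point radius grid, 20 random 64 x 64 instances for
the search-equivalence check (radius step 1 px there; the fine 0.2 px
grid is exercised by the recovery tests), 1000 null replicates for the
type-I calibration. Everything that draws random numbers takes a seed;
`run_pipeline()` writes a manifest (config echo, seed, version) and
timestamp-free outputs, so identical config + seed reproduce the
artifacts byte for byte.

## Known limitations

* Circle centers are searched on the integer grid; only the radius is
  sub-pixel. Scenes with deliberately fractional centers would add a
  sub-pixel center bias of up to ~0.5 px to the radius.
* The detector assumes the recorder's controlled geometry (one eye,
  roughly centered, iris fully visible); it is not a general-purpose
  eye tracker and does not fit ellipses, so strong off-axis gaze is out
  of scope.
* Glint screening relies on reflections being near-saturated, true for
  IR LED glints but not for dim stray reflections.
* The synthetic generator's noise is white; real sensor noise and
  hippus are temporally correlated, so the quoted sub-pixel accuracies
  are upper bounds on clean data, not field performance.

## A worked example

```{r example, eval = FALSE}
model <- plr_model()
protocol <- single_flash_protocol()
truth <- generate_ground_truth(model, protocol)
frames <- render_sequence(eye_scene(seed = 1), truth)
meas <- measure_sequence(frames, fps = 30)
trace <- build_trace(meas, 30, protocol, meas$iris_radius_px[1])
extract_single_flash(trace)
```
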