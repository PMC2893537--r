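# plrkit — dynamic pupillometry toolkit

`plrkit` measures the pupil light reflex (PLR) from infrared eye-image
sequences and reduces each recording to the standard screening
parameters used in autonomic-neuropathy research. The pupil constricts
after a light flash (parasympathetic drive) and redilates
(sympathetic drive); abnormal size, latency or amplitude of this reflex
is an early marker of autonomic dysfunction in diabetes. The package is
aimed at researchers who have such recordings — or who want a fully
controlled synthetic test bed for pupillometry algorithms.

It implements, as tested R code:

* **Synthetic data with exact ground truth** — an analytic reflex model
  (baseline hold, linear constriction, exponential recovery toward a
  plateau; geometric baseline adaptation under 1 Hz flash trains) and an
  anti-aliased eye-image renderer (dark pupil at gray 35, iris annulus,
  four IR glints, eyelid occlusion, blinks, noise).
* **Per-frame detection** — the offline measurement chain: glint
  elimination (Canny 0.8, contour filling, fill to gray 35), high-boost
  edge enhancement with a 0.6-gamma transform, Canny 0.5 pupil-edge
  detection, and circle fitting by maximum normalized correlation with
  annular templates over radii 20–90 px at 0.2 px resolution
  (sub-pixel radius, integer centers); iris localization by circular
  Hough transform.
* **Pupillogram parameterization** — single-flash and 25-flash (1 Hz)
  parameter sets: the pre-flash pupil/iris ratio, latency to
  constriction (radius down to 90% of baseline), latency/ratio at the
  largest constriction, plateau (back up to 75% of baseline), reflex
  amplitude, duration and velocity of constriction; blink detection
  with the more-than-three-blinks exclusion rule.
* **Cohort statistics** — per-parameter group tables (mean ± n−1 SD),
  one-way ANOVA with Bonferroni post-hoc for the healthy-vs-diabetic
  contrasts and Kruskal–Wallis for the diabetic-vs-diabetic contrast,
  with the */#/$ significance notation.

Formally, the circle fit maximizes over radius *r* ∈ {20.0, 20.2, …,
90.0} and integer centers *c* the normalized correlation
ρ(c, r) = ⟨T̃꜀ᵣ, Ẽ⟩ / (‖T̃꜀ᵣ‖‖Ẽ‖), where E is the binary edge map and
T꜀ᵣ the anti-aliased ring template of unit thickness, both centered to
zero mean; ties resolve to the smaller radius, and a score under the
convergence floor flags the frame invalid (the blink signal).

## Worked example

Render a 3 s single-flash recording from a known model, measure every
frame, and extract the reflex parameters:

```r
library(plrkit)
model    <- plr_model()                    # baseline 60 px, min 42 px, iris 110 px
protocol <- single_flash_protocol()        # flash at 0.5 s, 3 s at 30 fps
truth    <- generate_ground_truth(model, protocol)
frames   <- render_sequence(eye_scene(seed = 1), truth)
meas     <- measure_sequence(frames, fps = 30)
trace    <- build_trace(meas, 30, protocol, meas$iris_radius_px[1])
extract_single_flash(trace)
#> Single-flash parameters:
#>   baseline_radius_px                       60.0000
#>   ratio_PI_darkness                        0.5454
#>   latency_to_constriction_s                0.4400
#>   min_radius_px                            42.0000
#>   ratio_PI_largest_constriction            0.3818
#>   latency_to_largest_constriction_s        0.9000
#>   plateau_radius_px                        45.0000
#>   ratio_PI_plateau                         0.4090
#>   latency_to_plateau_s                     1.3667
#>   duration_of_constriction_s               0.4600
#>   reflex_amplitude_px                      18.0000
#>   velocity_of_constriction_px_per_s        39.1304
```

Reading the output: the dark-adapted pupil fills 0.545 of the iris and
constricts by 18 px (to ratio 0.382) with the minimum 0.9 s after the
flash; the radius falls through 90% of baseline 0.44 s after the flash
and regains 75% of baseline 1.37 s after it — all matching the
generating model's closed-form values to within one frame (1/30 s).
Every number here was measured from the rendered images, not read from
the generator.

A cohort-level run (three groups with published-ratio separations,
ANOVA + post-hoc table):

```r
cohort <- generate_synthetic_cohort(n_per_group = c(16, 16, 8), seed = 3)
pars   <- cohort_parameters(cohort)
build_results_table(pars[, c("group", "ratio_PI_darkness", "reflex_amplitude_px")])
```

A shell entry point with `simulate` / `detect` / `extract` / `stats` /
`run` subcommands is installed at `inst/cli/plrkit.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/plrkit.R", package="plrkit"))')" \
    run --config config.yaml --out results/ --seed 1
```

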