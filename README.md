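# sgrtrack

Marker-based optical surface tracking analysis for **upright radiotherapy
positioning**.

Upright treatment platforms seat the patient on a rotating chair and deliver
fixed horizontal beams, which makes setup reproducibility and intra-session
stability of the seated posture a central quality question. `sgrtrack`
implements the full analysis chain used to quantify that accuracy from a
three-camera optical rig imaging 26 dark circular markers on the patient's
skin and thermoplastic mask:

1. **Camera geometry** — pinhole projection with optional Brown–Conrady
   distortion, extrinsic calibration by nonlinear reprojection-error
   minimisation against a 41 × 58 grid plate (5 mm pitch), pairwise DLT
   triangulation with Gauss–Newton refinement, and held-out grid-plate
   verification of the reconstruction accuracy.
2. **Marker detection** — per-marker image patches, Otsu (or fixed)
   binarization and sub-pixel centroids of the dark pixels.
3. **Rigid registration** — Kabsch/Procrustes fits inside an iterative
   closest point loop; body and mask tracked separately per frame against the
   reference frame, with a 5-frame moving average suppressing respiratory
   motion of the abdominal skin markers before registration.
4. **Motion metrics** — 6-DoF displacement series (LR/AP/SI in mm, positive
   toward left/anterior/superior; pitch/roll/yaw in degrees about LR/AP/SI),
   the relative body-to-mask transform `M_rel = M_body · M_mask⁻¹`,
   inter-fractional setup-error statistics, and beam delivery time (BDT)
   under tolerance thresholds (±2 mm/±1° abdominal, ±1.5 mm/±1° head-neck).
5. **Statistics** — Welch's *t*-test, the Brown–Forsythe variance test, and
   Holm–Bonferroni adjustment across setup-pair families at α = 0.05.
6. **Synthetic scenes** — a simulator that generates every pipeline input
   (rig, layouts, saturating drift, aliased respiration, mask-relative
   motion, 4% dropout, sub-pixel noise) with ground truth alongside, so the
   whole chain is testable without clinical data.

Setup-error notation follows the standard decomposition: for per-subject,
per-repetition errors the overall mean is **μ**, the *systematic* component
**Σ** is the SD over subjects of the per-subject means, and the *random*
component **σ** is the mean over subjects of the per-subject SDs (n−1
denominators throughout).

## Worked example

A 10-minute abdominal tracking session, simulated, triangulated and tracked
end to end:

```r
library(sgrtrack)

cfg    <- scene_config(setup = "abdominal", seed = 42, duration_s = 600)
sim    <- simulate_intrafraction(cfg)
clouds <- triangulate_detections(sim$detections, sim$cameras, sim$layout)
track  <- track_sequence(clouds, setup_type = "abdominal")
origin <- set_origin(dplyr::filter(clouds, frame == 0), "abdominal")
series <- displacement_series(track, origin)

glance(track)
#> # A tibble: 1 × 5
#>   setup_type n_frames n_registered mean_rms_body_mm mean_rms_mask_mm
#> 1 abdominal       121          121            0.200            0.226

tidy(bdt(dplyr::filter(series, object == "body"),
         default_tolerance("abdominal")))
#> # A tibble: 7 × 3
#>   axis  tolerable_min convention
#> 1 all            9.08 cumulative
#> 2 lr            10    cumulative
#> ...
```

All 121 frames register with ~0.2 mm residuals (0.5 px detection noise at
~5 px/mm). The body stays inside the ±2 mm/±1° abdominal tolerance for
9.08 of the 10 minutes; the limiting axis is SI, where the simulated
saturating drift (−2 mm amplitude, τ = 150 s) eventually crosses the
threshold — the same anterior/inferior early-drift pattern seen in seated
subjects. `autoplot(series)` draws the six-panel displacement time course.

An inter-fractional ensemble and its μ/Σ/σ table:

```r
inter <- simulate_interfraction(cfg, n_subjects = 15)
tidy(interfraction_summary(inter$truth))
#> # A tibble: 7 × 5
#>   axis       mu sigma_systematic sigma_random n_subjects
#> 1 lr    -0.366              1.30         1.11         15
#> 2 ap    -0.0864             1.79         1.64         15
#> 3 si     0.336              2.58         1.21         15
#> ...
```

With 15 subjects the recovered Σ/σ sit near the generator's per-axis inputs
(systematic 1.4/1.7/2.2 mm, random 1.3/1.6/1.4 mm for LR/AP/SI), with the
sampling scatter a 15-subject study implies.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full demonstration pipeline from scratch against the
installed package — grid-plate verification on a held-out pose, the complete
20-minute intra-fractional chain (simulate → triangulate → track →
displacement series → BDT), a 12-subject inter-fractional summary and the
two-setup statistical comparison — prints the session-level summary numbers
it computed, and writes the acceptance JSON to `--out`.

## Layout

- `R/` — geometry, camera model, calibration, detection, registration,
  metrics, statistics, simulator, pipeline/IO, tidiers, plots.
- `tests/testthat/` — unit and property suites per module plus
  `test-acceptance.R` with the pipeline-level acceptance properties.
- `vignettes/surface-tracking.Rmd` — the methods vignette: model,
  conventions, parameter choices, what the simulator does and does not
  emulate, numerical decisions and limitations.
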