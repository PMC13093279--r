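---
title: "Surface-tracked setup accuracy for upright radiotherapy: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-tracked setup accuracy for upright radiotherapy: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgrtrack)
```

## The measurement problem

Upright radiotherapy seats the patient on a rotating chair in front of fixed
horizontal beams. Whether a seated posture can be reproduced between
sessions (inter-fractional setup error) and held steady within a session
(intra-fractional displacement) is measured here optically: three
high-resolution cameras (front, left, right) image 26 dark 5-mm markers
placed on the body surface and on the thermoplastic immobilization mask,
a calibrated rig triangulates each marker into 3D, and rigid registration
against a reference frame turns the marker clouds into six-degree-of-freedom
motion of the body and of the mask.

The package implements that chain end to end, plus the downstream
statistics, plus a simulator that produces every input with known ground
truth. Everything operates in one fixed world frame: x = LR (positive
toward patient left), y = AP (positive anterior), z = SI (positive
superior), lengths in mm, a right-handed basis. Displacement signs follow
the same convention: a positive AP displacement means the body moved
anterior relative to the reference image.

## Camera model and calibration

Cameras are standard pinholes with optional Brown–Conrady distortion
(`k1,k2,k3,p1,p2`; all zero in the default synthetic rig, supported
throughout when supplied). Intrinsics are *inputs* — the planar-target
method that produces them is a routine prior step outside this package's
scope. Extrinsics are estimated by `calibrate_extrinsics()`:
Levenberg–Marquardt over the six pose parameters (Rodrigues rotation vector
plus translation), minimising the summed squared pixel distance between
detected grid-plate points and the projections of their known 3D positions.
The grid plate is 41 × 58 points at 5.0 mm pitch (2378 points); six plate
poses supply the calibration observations and a seventh, held-out pose
feeds `verify_grid()`, which reports per-axis absolute-error and 3D-error
means, SDs and 95th percentiles per camera pair — the standard way of
certifying such a rig at sub-millimetre level.

Numerical choices: the LM normal equations are damped multiplicatively
(factor 10) with a diagonal-scaled identity; convergence is declared on a
relative cost decrease below 1e-14, which drives noiseless fixtures to
machine precision — the test suite requires pose recovery to 1e-6 mm /
1e-7 degrees there. Percentiles use linear interpolation between order
statistics (R type 7); the choice is recorded with the report and verified
against a brute-force sort-and-interpolate oracle.

`triangulate_pair()` computes the direct-linear-transformation estimate
from the two undistorted pixel observations and refines it by Gauss–Newton
on the reprojection residuals. Rays closer than 0.5 degrees to parallel
raise an error rather than returning an ill-conditioned point. Camera pair
selection mirrors clinical practice: left-side markers use (front, left),
right-side and central markers (front, right), and the lateral (left,
right) pair serves only as fallback when the front view is missing; fewer
than two valid views flags the marker invalid — never silently dropped.

## Marker detection

Detection runs per marker inside a static patch box: binarize, then take
the centroid of the dark pixels. Otsu's threshold per patch is the default
(the field-standard choice when no threshold is published), with a fixed
threshold available in the configuration. The pixel-coordinate convention
is fixed and bit-exact: 0-based pixel (i, j) has centre (u, v) = (j, i),
and the centroid is the plain mean of dark-pixel centres plus the patch
offset. Detections with fewer than `min_area = 10` dark pixels are invalid
— this absorbs occluded, removed or covered markers.

A binarized centroid is quantization-limited: with the default rig
(25 mm lens, 2.4 µm pixels, ~2 m range) a 5-mm marker is ~13 px in radius,
and including-or-excluding ~80 boundary pixels limits accuracy to a few
hundredths of a pixel on average (worst case ~0.1 px), improving only with
the square root of the radius. The test suite asserts the honest bounds
(mean < 0.08 px, max < 0.2 px against rendered ground truth) and exactness
against the enumeration oracle; consequently the end-to-end
recovery test at the 1e-3 mm level runs on the simulator's exact projected
detections, which is also what the pipeline consumes by default.

## Registration and tracking

`kabsch()` is the closed-form SVD fit with the determinant correction that
excludes reflections; `icp()` wraps it in the classic alternation with
nearest-neighbour correspondences (point-to-point — the clouds are labelled
markers, not surfaces). A `labeled` mode uses the marker labels as fixed
correspondences and serves as the oracle path: on the default layouts,
whose minimum marker spacing (> 20 mm) is far above the millimetric
clinical motions, nearest-neighbour and labelled registration agree to
1e-9, a property the suite checks on 200 random scenes. Only markers valid
in *both* clouds participate; fewer than three flags the frame
unregistered, and the pipeline continues. ICP defaults (50 iterations,
1e-6 mm RMS-change tolerance, identity initialisation) reflect that
millimetric motions keep identity inside the convergence basin; the RMS
trace is retained and its monotone non-increase asserted on every run.

Respiration makes the nine abdominal skin markers (A1–A9) move non-rigidly,
so their positions are smoothed over five frames before registration —
during intra-fractional tracking only; single inter-fractional images are
never smoothed. The wording "five subsequent frames" leaves the window
alignment open; the package uses a **centred** moving average (phase-neutral,
so the displacement series is not lagged) whose window shrinks symmetrically
(5 → 3 → 1) at the series edges. The symmetric shrink matters: a truncated
asymmetric window at frame 0 would shift the smoothed reference cloud by a
fraction of the respiratory amplitude and bias every subsequent
displacement. A trailing (causal) mode is provided for real-time-style
reprocessing. At the 5-s cadence a ~4-s breathing cycle aliases to 0.25
cycles/frame, where the 5-frame average has gain
|sin(5πf)/(5 sin(πf))| = 0.2 — the suite verifies the residual leakage
against exactly this closed form.

Thigh markers A10–A11 are excluded from the body registration and reported
as raw per-marker displacement vectors (they monitor leg stability, not the
rigid torso). The reporting origin of all transforms sits on the chair's
vertical rotation axis — 15 cm anterior to the backrest plane — at the SI
height of the anchor marker (A2 abdominal, H1 head-neck) in the reference
cloud. Transforms map reference-frame coordinates to current-frame
coordinates, so a reported displacement reads directly as "where the body
moved relative to the reference image".

## 6-DoF decomposition

Translations are the motion of the reporting origin, `T(o) − o`. Rotations
are Euler angles of the rotation part. No Euler convention is canonical for
this problem, so one is fixed and documented: intrinsic yaw–pitch–roll
(about SI, then LR, then AP), right-hand rule about each positive axis,
reported in degrees. The choice is numerically immaterial at clinical
magnitudes: sequence differences are second order in the angles
(~0.016° worst case at 1° on all three axes, < 0.002° below 0.3°), a
property the suite measures directly, with the quadratic scaling. The
translation part obeys `t_o = t_0 + (R − I)·o` exactly, and
`from_displacement()` inverts `to_displacement()` about the same origin to
1e-9 over a thousand random small transforms. Gimbal proximity (|pitch|
near 90°) is flagged but unreachable for clinical motion.

## Motion metrics

`interfraction_summary()` implements the standard decomposition: per axis,
μ = mean of per-subject means, Σ = SD (n−1) over subjects of per-subject
means, σ = mean over subjects of per-subject SDs (n−1). The 3D row applies
the same definitions to per-repetition Euclidean norms of the translations
(rotations are reported separately, as in the usual translation/rotation
table split). Two estimator facts worth knowing when reading recovery
tests: the per-subject SD underestimates its population value at 5
repetitions (E[s] = c₄(5)·σ ≈ 0.94σ), and the SD of subject means includes
a σ²/m leakage term — both are properties of the standard definitions, not
of this implementation, and the acceptance suite documents one marginal
red outcome caused by the first.

`bdt()` counts beam delivery time: the default **cumulative** convention
sums every within-tolerance frame after the reference as one full 5-s
interval (a fully compliant 241-frame session yields exactly 240 × 5 s =
20 min); an **until-first-violation** convention is selectable, and results
carry their convention tag. Six per-axis tolerable times use the same
counting per component; the total is never greater than their minimum, and
enlarging thresholds never decreases BDT — both asserted properties.
Default thresholds are ±2 mm/±1° (abdominal) and ±1.5 mm/±1° (head-neck).

## Statistical layer

Welch's *t* (with Welch–Satterthwaite df), the Brown–Forsythe test (one-way
ANOVA F on absolute deviations from group medians) and Holm–Bonferroni
step-down adjustment are implemented at formula level and cross-checked in
the tests against `stats::t.test`, `stats::anova(lm(...))` and
`stats::p.adjust` — two independent routes to every number. All p-values
are two-sided. `compare_setups()` applies both tests per setup pair and
Holm across the pair family (separately per test); a single two-setup
contrast runs unadjusted. One caveat the suite quantifies: the
Brown–Forsythe F approximation is conservative in small groups, so its
nominal-level check runs at n = 30 per group, the moderate-sample regime
where the approximation holds.

## The simulated world

The simulator's defaults are a stated world, fixed once:

| parameter | default | rationale |
|---|---|---|
| session | 1200 s at 5 s cadence (241 frames) | the 20-min protocol |
| image size | 5496 × 3672 px | the rig's sensors |
| optics | 25 mm lens, 2.4 µm pitch (fx ≈ 10417 px) | sensor-native pitch of the class of camera used |
| rig | cameras 2 m from the rotation axis at 0/±55° azimuth | covers the subject volume with >20° ray separation everywhere |
| drift | A·(1−e^(−t/τ)), τ = 150 s; AP +1.5 mm, SI −2 mm, LR 0.3 mm; ≤0.3° rotations | saturating drift, largest over the first ~5 min, anterior and inferior |
| respiration | 2 mm AP / 0.5 mm SI sinusoid, 4 s period, on A1–A9 only | abdominal surface breathing amplitude; deliberately aliased by the 5-s cadence so only the smoothing suppresses it |
| mask drift | independent saturating drift ≤0.4 mm / τ = 300 s composed onto the body motion | small mask-relative-to-body motion |
| dropout | 4% per marker-frame (non-reference frames) | observed fraction of undetectable markers |
| pixel noise | 0.5 px SD | sub-pixel detection scatter |
| inter-fraction Σ\*/σ\* | per-axis mm: (1.4, 1.7, 2.2)/(1.3, 1.6, 1.4); deg: (0.8, 0.8, 0.5)/(0.4, 0.5, 0.5) | the masked abdominal setup's reported spreads |

Marker coordinates and camera placement are invented but geometrically
plausible (the clinical layouts are unpublished): an elliptic-cylinder
torso carries A1–A9, thigh markers sit at mid-thigh, and mask markers lie
on an anterior shell offset >20 mm from the skin markers so that
nearest-neighbour ICP can never cross-assign at clinical motion scales.
All randomness flows from one master seed through fixed per-stage
substreams, so any stage reruns bit-identically.

What the simulator does **not** emulate: photorealistic shading, skin or
clothing deformation, occlusion geometry (dropout is random, not
line-of-sight), camera time lag, thermal drift of the rig, or chair
rotation. A green end-to-end test therefore establishes that the *analysis
chain* is correct on data whose generative structure matches the stated
motion model — it does not certify performance on clinical images.

## Limitations

- Rigid-body registration only; deformable surface motion is out of scope
  by design, and respiratory non-rigidity is handled by smoothing, not
  modelled.
- Binarized-centroid detection is quantization-limited (~0.05 px scale);
  gray-weighted centroids would do better but would not be the procedure
  under study.
- The μ/Σ/σ definitions carry their standard small-sample biases (see
  above); no deconvolution is applied.
- Surface motion is a surrogate: correlation with internal anatomy is not
  addressed.
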