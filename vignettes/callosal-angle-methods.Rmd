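---
title: "Measuring the callosal angle: model, geometry and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the callosal angle: model, geometry and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caliper)
```

## The measurement problem

The callosal angle (CA) is the opening between the medial walls of the
two lateral ventricles, read on a coronal plane that is perpendicular to
the line joining the anterior and posterior commissures (AC, PC) and
passes through the PC. In normal pressure hydrocephalus the ventricles
balloon upward against the corpus callosum and the angle narrows; a 90°
threshold is the conventional narrow/wide cutoff. The angle is only
well-defined once the slice orientation is fixed — a pitch error of a few
degrees or a PC localization error of a few millimetres moves the slice
onto a differently-shaped part of the ventricles and changes the angle —
which is why the pipeline treats plane construction as a first-class
geometric step and ships a perturbation experiment to quantify exactly
that sensitivity.

`caliper` implements the full deterministic chain from a raw T1 volume
and a pair of AC/PC coordinates to the angle. The two learned components
of a production system — a landmark detector and a ventricle segmenter —
enter only through provider contracts (`function(volume) -> landmarks`,
`function(slice) -> mask`), for which the package supplies file-based
implementations and analytic phantom implementations. Training or
bundling networks is out of scope.

## Pipeline geometry

**Preprocessing.** The volume is reoriented to RAS by axis permutation
and flips derived from the affine (an affine whose voxel axes are all
more than 45° from the canonical axes is rejected with advice to
resample). It is then resampled with trilinear interpolation into an
isotropic cube (default edge 128) whose largest physical extent spans the
cube; remaining axes are scaled by the same factor — aspect ratio is
preserved — and padded symmetrically with the volume minimum, a
background proxy. The mm-per-cube-voxel `scale_factor`, pad offsets and
source affine are retained, so cube, source-voxel and world (mm)
coordinates interconvert exactly. Intensity standardization is
per-volume (the usual choice when no training population is available):
mean and SD are computed over the non-padded content box only, so the
padding cannot bias the moments, and the whole cube is transformed by
the same affine map.

**Plane frame.** With `n = unit(AC − PC)` (anterior at baseline), the
in-plane axes are `u` — the subject left→right axis projected into the
plane and renormalized — and `v = u × n`, which points superior. Slice
pixel `(i, j)` (0-based, rows increasing inferiorly, columns toward the
subject's right) samples `origin + (j − cx)·s·u + (cy − i)·s·v` with
`(cx, cy) = floor(size/2)`, so the PC lands on a pixel center. The
default slice is 224 × 224 pixels at `s = edge/224` cube voxels per
pixel: the coronal section of the cube resized onto the segmenter's
input grid. (A spacing of 1 voxel per pixel would make a 224-pixel slice
span 224 voxels of a 128 cube, mostly background; it remains available
through `ca_config(slice_spacing = )`, and axis-aligned identity tests
use it deliberately.) Intensities are sampled trilinearly, label volumes
nearest-neighbour, out-of-volume pixels get the background value.

**Separating line.** For disjoint contours the maximum-margin separating
line is computed exactly from convex geometry: the optimal separator is
the perpendicular bisector of the shortest segment between the convex
hulls of the two contours, and the margin is half that distance — the
same optimum a hard-margin linear SVM converges to, but closed-form and
deterministic (the test suite cross-checks against `e1071`'s libsvm and
against an exhaustive angle sweep). If the hulls intersect, the overlap
area is estimated on a grid; overlap beyond 20% of the smaller contour
raises an error, otherwise a deterministic 0.1°-step direction sweep
returns the most-separating line and the result is flagged
`soft = TRUE` in the diagnostics.

**Medial walls, base points, wall lines.** Rays perpendicular to the
separating line are cast every `ray_step` (1 px) from stations spanning
the contours' projected extent, toward each side; the first intersection
with that side's contour polygon is a medial-wall point, and rays that
miss are skipped. Base points follow the contact rule: among a
ventricle's contour points within `max(threshold, d_min + 1 px)` of the
other contour (`d_min` the minimal inter-contour distance, so candidates
always exist; `threshold` defaults to 5 px), the most superior point is
selected, with ties broken by smaller distance to the other contour and
then by the medial-most position. Candidates are taken on the densely
resampled contour polyline (0.25 px) rather than its vertices only, so
the choice is not biased by where the contouring algorithm happened to
place vertices. The wall line is constrained to pass through the base
point; directions are swept over (−90°, 90°] from vertical in
`angular_step` (0.25°) increments and scored by the number of wall
points within `wall_tol` (1.5 px) of the line — an inlier-maximizing
search in the RANSAC spirit, but exhaustive over the one free parameter
and therefore deterministic. Ties are resolved by minimal inlier RMS,
then by the smaller angle from vertical. The angle between the two
inferior-oriented wall directions is the CA; angles strictly below the
90° threshold classify as narrow (exactly 90° is wide, consistent with
the strict inequality used for PCK@10).

### Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `edge` | 128 | voxels | preprocessing cube edge |
| `slice_size` | 224 × 224 | px | slice/segmenter input size |
| `slice_spacing` | `edge/224` | voxel/px | slice pixel pitch |
| `ray_step` | 1 | px | station spacing along the separating line |
| `wall_tol` | 1.5 | px | inlier tolerance of the wall-line search |
| `angular_step` | 0.25 | ° | wall-line sweep resolution |
| `base_threshold` | 5 | px | base-point contact threshold |
| `classify_threshold` | 90 | ° | narrow/wide cutoff |

Halving `ray_step` or `angular_step` moves phantom angles by well under
0.5° (tested), so the defaults sit on the flat part of the
discretization curve. Every result echoes the effective configuration.

## The wedge phantom and what it does (not) validate

`make_wedge_slice()` builds a 2D cross-section with two wedge-shaped
"ventricles": each medial edge descends from a corner near the apex at
±apex/2 from vertical, the body extends laterally with fixed horizontal
width, the roof is flat for 2 px beside the medial corner and then
slopes gently downward laterally (ventricular roofs are highest at the
midline; the ledge also keeps the rasterized apex connected at any wall
slope), and the two medial edges are `gap` apart at apex level. The
ground-truth CA equals the apex angle by construction and the analytic
wall lines are returned. The apex sits off the pixel lattice by default
so that rasterization phases are not systematically aligned with the
grid. Intensities are a lightly smoothed mask plus seeded Gaussian
noise; all randomness is behind the single `seed` field.

`make_phantom_volume()` extrudes this cross-section along the
anterior–posterior axis of a 1 mm isotropic 128³ RAS volume, with AC and
PC placed on the extrusion axis 26 voxels apart (a typical AC–PC
distance). Two features emulate real anatomy deliberately:

* the apex angle varies smoothly along the axis,
  `apex(y) = apex₀ + A·(cos((y − y_PC)/λ) − 1)` with A = 16°, λ = 8
  voxels, equal to the nominal angle exactly at the PC. Real ventricular
  cross-sections change shape along the AC–PC axis — that is precisely
  why PC mislocalization biases the CA — and without this the PC-shift
  perturbation would measure nothing and its paired t-test would
  degenerate (zero variance). The resulting sensitivity (≈3° at ±5
  voxels, ≈11° at ±10) is of the same order as clinically reported
  shift sensitivities;
* wall length grows as the angle narrows (lateral reach is capped at 40
  voxels), matching the long steep walls of narrow-angle ventricles, and
  the width drifts slowly along the axis.

Optional rigid tilts rotate the solid and the landmarks jointly, so a
correct pipeline must recover the same angle from the oblique plane. The
phantom segmenter evaluates the analytic solid on whatever plane it is
asked to segment — the exact stand-in for a perfect segmentation
network, limited only by pixel rasterization.

What passing phantoms shows: the geometry chain (reorientation, oblique
resampling, contouring, separation, ray casting, line fitting) is
correct to 1–2.5° at clinical resolution, is mirror- and
rotation-stable, and responds to plane perturbations the way the slice
geometry predicts. What it does not show: performance under real MR
contrast, partial-volume and segmentation errors, anatomical variants
(asymmetric horns, cavum septi), or imperfect landmark detectors — all
of which live in the providers that the phantoms deliberately idealize.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based and address voxel centers; world
  coordinates are RAS mm.
* Contours are traced at the 0.5 iso-level (subpixel marching squares)
  on zero-padded class indicators, so regions touching the border still
  close; the largest closed boundary per class is kept; classes smaller
  than 5 px are errors.
* Dice of an empty-vs-empty class is defined as 1, empty-vs-nonempty as
  0 (the formula is 0/0 there); Hausdorff distances are boundary-based
  and scale with pixel spacing when known.
* PCK@10 uses a strict inequality (error < 10% of the AC–PC distance),
  as does the narrow classification (CA < 90°).
* The perturbation rotations pivot at the plane origin (the PC), are
  applied sagittal-then-axial (non-commutativity below 10° is < 0.02°,
  but the order is fixed for reproducibility), and PC shifts run along
  the unperturbed normal, positive anterior, in cube voxels with the mm
  equivalence given by `scale_factor`.
* Degenerate inputs raise typed, stage-named errors: AC = PC; AC–PC
  parallel to the left–right axis (roll undefined); constant intensity;
  overlapping ventricles; walls with fewer than 3 ray hits or inliers;
  zero-variance paired differences.
* Bland–Altman limits use the conventional bias ± 1.96·SD (sample SD);
  differences are predicted − reference throughout.

## Problem sizes used in validation

The shipped tests and the acceptance script use: five apex angles
{60, 80, 100, 120, 140}° for noiseless 2D recovery; a 135-run 3D grid
(5 angles × tilts {0, 5, 10}° applied as sagittal with half-magnitude
axial × noise SD {0, 0.05, 0.1} × 3 seeds); 25-instance oracle suites
for the separating line (vs an exhaustive 0.1° sweep with per-angle
optimal offset) and the wall line (vs a 0.01° exhaustive sweep); a
24-phantom agreement cohort; and 20 phantoms × offsets {±5, ±10} per
axis for the perturbation experiment. These sizes make every stage's
error measurable against analytic truth while keeping a full validation
run to minutes on a single CPU.

## Known limitations

* The CA depends on rasterization at 128³/224²: phantom recovery is
  accurate to about 1–2.5° and carries a small negative bias (the
  pinned base point sits on the dilated iso-contour). Reported agreement
  statistics on phantoms reflect that floor, not clinical accuracy.
* The base-point rule assumes the ventricles approach each other near
  the callosal apex; pathologies where the closest approach is far from
  the apex would need a different contact threshold.
* The wall-line model is a straight line per side, appropriate where the
  medial walls are locally linear at the PC level; strongly curved walls
  are averaged by the inlier criterion.
* Only the in-plane 2D measurement is implemented; ventricular
  volumetry and the Evans index are outside this package's scope.
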