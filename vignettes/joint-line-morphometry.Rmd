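---
title: "Joint-line morphometry of the distal femur: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-line morphometry of the distal femur: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jlmorph)
```

## The measurement model

In knees with severe femoral bone loss the articular surfaces (AS) that
define the joint line (JL) are missing, but the epicondyles usually remain.
`jlmorph` measures, on an intact distal femur, how far the joint lines lie
from the epicondylar prominences, and expresses the distances as fractions
of the transepicondylar width so that they transfer across knee sizes.

The frame in which those distances are defined is built entirely from the
bone surface:

1. **Anatomical axis.** At 100 mm and 150 mm proximal to the distal JL, the
   shaft cross-section (a slab of ±2 mm) is reduced to the midpoint of its
   most medial and most lateral surface points, evaluated in the working
   coronal projection; the axis joins the two midpoints. This mirrors the
   radiographic construction of the shaft axis on an AP view. "Femoral
   width" at a shaft level is not otherwise defined for a 3D surface, so
   the medial–lateral extent in coronal projection is used; the midpoint is
   the mean of the two extreme points.
2. **Mechanical axis.** The anatomical axis rotated by a fixed valgus angle
   (default 6°, configurable) about the anterior direction, anchored at the
   distal anatomical-axis point. The rotation sense carries the proximal
   end of the axis toward the medial side: the femoral shaft runs
   proximally lateral to the hip centre, so the hip-to-knee (mechanical)
   line is the shaft axis tipped medially at the top. The side must be
   supplied by the caller; it is not guessed from the mesh.
3. **Axial plane** perpendicular to the mechanical axis.
4. **Epicondylar prominences.** Within an axial band over the condylar mass
   (distal JL level to 2 × 20 mm above it, configurable), the surface
   points extremal along the ±ML direction. The prominence, not the
   sulcus, is the reference: it is the point this construction finds, and
   it is the landmark that remains palpable and visible on CT.
5. **Clinical transepicondylar axis (c-TEA)** through the two prominences,
   and the **coronal plane** spanned by the c-TEA direction and the
   mechanical-axis direction through the transepicondylar midpoint.
6. **Condylar extremes.** The mesh is split at the mid-sagittal plane
   (through the c-TEA midpoint, normal along the c-TEA); per side, the
   posterior-most point (for the posterior condylar line, FJ) and the
   distal-most point along the mechanical axis (for the distal articular
   line, EJ).

The construction is circular — the anatomical axis is referenced to the
distal JL, which needs the mechanical axis — so `build_frame()` iterates
the whole chain to a fixed point (landmark displacement < 0.1 mm, at most
10 iterations by default; noise-free synthetic bones converge in 3).

Per knee, `measure_knee()` then reports

* `me_fj`, `le_fj`: perpendicular distances from ME/LE to the FJ line,
  both projected into the axial plane;
* `me_ej`, `le_ej`: perpendicular distances to the EJ line in the coronal
  plane;
* `ml`: the 3D chord ME–LE (the axial plane is where the prominences are
  located, not a plane the width is projected into);
* the four ratios `distance / ml`.

Distances are unsigned: on anatomically valid input the epicondyles always
lie anterior/proximal to the respective joint lines, so the sign carries no
information. Angles are degrees at every public interface; lengths are mm.

## Ratio-based prediction

`predict_offsets(ml, ratios)` multiplies a measured width by each ratio and
rounds half away from zero to integer millimetres — the resolution at which
distal/posterior augmentation is planned. The packaged
`default_ratio_table()` is (0.39, 0.28, 0.33, 0.28) for
ME-FJ/ML, LE-FJ/ML, ME-EJ/ML, LE-EJ/ML, the means of the reference CT
cohort of 127 varus knees (Kellgren–Lawrence grade ≤ 2) on which this
methodology was established. For a 67 mm femur this yields 22 mm (distal,
from the ME) and 26 mm (posterior, from the ME):

```{r predict}
predict_offsets(67)
```

The 6% ML gap between the two medial offsets (~4 mm at typical widths)
reflects the anatomy of the prominence reference: the medial sulcus lies
3–4 mm posterior to the prominence, which is why prominence-referenced
posterior ratios run higher than distal ones.

## The synthetic femur generator

No CT data ship with the package; every downstream stage is validated on a
parametric femur with analytic ground truth.

**Landmark level.** `build_landmarks()` places the six landmarks in a
canonical frame (mechanical axis = +z proximal, medial = +x on the right,
anterior = +y) such that measuring them in the true frame returns the
specification's five distances exactly (machine precision). The two joint
lines are slanted so that the medial and lateral perpendicular distances
are both honoured, and each condylar landmark pair is realized as the
posterior-most and distal-most point of one axis-aligned ellipsoid.

**Mesh level.** `build_mesh()` samples a surface from four primitives —
a shaft cylinder (oblique at 6° to the mechanical axis, so the valgus
relation is part of the bone, radius 16 mm, length 200 mm so that both
shaft levels exist), two condylar ellipsoids whose extreme points are the
condylar landmarks, and two pointed epicondylar bumps whose apices realize
ML — at a target edge length (≤ 3 mm), then optionally jitters every vertex
coordinate with Gaussian noise. Secondary shape constants scale with ML
(condyle centres at ±0.25 ML, ML semi-axis 0.16 ML, distal semi-axis
0.19 ML; bump semi-axes 8/6/6 mm at the reference width): they were chosen
once for anatomical plausibility and play no role in the exactness of the
ground truth. The mesh is deliberately not watertight (patches overlap, as
segmentation surfaces often do); extreme-point detection does not require
it.

**Cohort level.** `sample_cohort_specs()` draws ML normal and each distance
from the single-factor model `D = mu_D + a (ML - mu_ML) + eps`, with the
slope and residual SD solved so that every marginal mean, marginal SD and
correlation with ML matches the configuration. The reference configuration
(`reference_cohort_config()`) uses the published means/SDs
(ML 75.1 ± 4.2, ME-FJ 29.4 ± 2.2, LE-FJ 21.2 ± 2.3, ME-EJ 25.1 ± 2.8,
LE-EJ 21.3 ± 2.5 mm) and ML-correlations (0.623, 0.396, 0.393, 0.445).
Only the correlations *with ML* are published; the single-factor model is
the minimal completion — it reproduces every stated moment and leaves the
unstated distance–distance correlations determined by shared dependence on
ML. Draws violating geometric constructability (`ml > me_fj`, positive
lengths) are redrawn; with the reference moments this is a far-tail event.
Where the source reports slightly different values in different places
(e.g. ME-EJ 25.2 vs 25.1), the primary results table wins; no
reconciliation is attempted.

**What the generator does not emulate.** Real femora have continuous
condylar curvature blending into the trochlea, cartilage (absent on CT,
a stated limitation of the methodology), cortical thickness, osteophytes
and segmentation artefacts beyond white vertex noise. Passing tests on
synthetic bones therefore demonstrate that the *frame construction and
measurement chain* is correct and robust to pose and noise — not that the
ratios themselves generalize to any particular patient population.

## Numerical choices

* **Tolerances.** 1e-9 on normalized quantities, 1e-6 mm on lengths
  (millimetre-scale anatomy in double precision leaves 9+ digits of
  headroom); frame convergence 0.1 mm, an order below the mesh resolution.
* **Damped fixed point.** On noisy meshes the frame map can two-cycle: a
  flip between two near-tied distal vertices shifts the distal JL level,
  which shifts the 100/150 mm shaft slabs, which tips the axis back. The
  working proximal direction is therefore updated with shrinking (1/k)
  weights, which averages such cycles out and leaves the fixed point
  unchanged; a final undamped pass rebuilds the frame so the stored
  mechanical axis is exactly at the valgus angle to the stored anatomical
  axis.
* **Sub-vertex landmark refinement.** The extreme *vertex* of a jittered
  surface is biased outward: among the many vertices that could be
  extreme, selection favours positive noise. `refine_landmark()` fits a
  quadratic height field over the local patch (two passes, re-centred) and
  returns its stationary point, which averages the noise and restores the
  smooth surface's tangent point; on noise-free surfaces the fit agrees
  with the analytic extremum to second order (~0.02 mm here). Patch radius
  should scale like the noise-competition length `sqrt(2 R sigma)`:
  3 mm at sharp prominences, twice that at the flat condylar extremes.
  Refinement is on by default (`frame_config(refine_landmarks = )`); the
  raw detections remain available and are what the exhaustive-scan oracle
  tests check.
* **Ties and degeneracies.** Tied epicondylar extremes break toward the
  band's axial midline; a near-spherical vertex cloud, an empty shaft
  slice, an empty condyle after the sagittal split, coincident joint-line
  points, and a line perpendicular to its measurement plane are all
  reported as errors, not guessed around.

## Statistics

* `summary_stat()`: mean, SD (n−1), and mean ± t(0.975, n−1)·SD/√n.
  Computations keep full precision; only display rounds.
* `pearson_cor()`: product-moment r with the two-sided p from
  t = r√((n−2)/(1−r²)).
* `icc_absolute_agreement()`: ICC(2,1) — two-way random effects, absolute
  agreement, single rater — from the ANOVA mean squares,
  (MSR − MSE)/(MSR + (k−1)MSE + k(MSC − MSE)/n). The reference analysis
  does not name its ICC form; ICC(2,1) is the standard choice for
  intra-/inter-observer landmark reliability, and the reliability check is
  a regime reproduction (simulated observers with 0.3 mm RMS landmark
  noise give ICC > 0.94 on all five distances), not an exact one.
* `correlation_power()`: the exact method integrates the sampling density
  of r under a bivariate normal with correlation ρ (Hotelling's form, with
  the Gauss hypergeometric series evaluated directly) beyond the critical
  r of the t-test; the Fisher-z method is the usual normal approximation.
  At ρ = 0.3, α = 0.05, n = 127 (two-sided) the exact method gives 0.933
  and Fisher-z 0.931; the exact value is confirmed by Monte-Carlo
  rejection rates in the test suite. Exact is the default and the method
  of record.

## Problem sizes used in validation

The test suite validates parameter recovery on 200 synthetic cohorts of
n = 127 at landmark fidelity, mesh-pipeline accuracy on 30 noise-free and
30 noisy (σ = 0.2 mm) meshes at 1 mm resolution under random rigid poses,
cohort-sampler moments at n = 10,000, and the exact power against a
50,000-draw Monte-Carlo. These sizes give sampling error comfortably below
the asserted tolerances while keeping the full suite around a minute.

## Known limitations

* The valgus angle is a configuration constant (default 6°) applied to
  every knee, as in the reference methodology; it is not estimated from a
  hip centre, which a CT of the full femur would permit.
* The coronal-plane definition follows the spanning-directions reading
  ("the plane containing the c-TEA and the mechanical axis direction");
  if the mechanical axis and the c-TEA were nearly parallel the plane
  would be ill-conditioned, but anatomically they are close to
  perpendicular.
* Ratios are means; the distance–width correlations are moderate, so
  individual knees deviate. The package reports raw offsets alongside
  rounded ones so the user can see how close a prediction sits to a
  rounding boundary.
* Cartilage is not modelled: on CT (and on the synthetic bones) the joint
  lines are bony tangents.
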