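---
title: "Virtual fitting of proximal femoral nails: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual fitting of proximal femoral nails: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femfit)
```

## The problem

Cephalomedullary nails for trochanteric fractures are designed around
population-average femoral geometry. In femora with a short neck, a
small neck-shaft angle, a narrow canal and pronounced anterior bowing of
the shaft — all more common in East-Asian patients — a nail placed
exactly according to the manufacturer's guidelines can conflict with the
inner cortex. The conflict shows up in two complementary ways: the nail
surface *impinges* on (penetrates) the endosteal surface, concentrating
stress, or it *deviates* from the cortex, leaving the construct poorly
supported. `femfit` formalizes the virtual fitting experiment: place a
parametric nail model into a landmarked endosteal femur model by the
guideline rules, quantify where and how much it impinges, and compare
nail designs over a paired cohort.

The package deliberately separates four stages, each testable on
analytic constructions:

1. **Nail geometry** (`nail_spec()`, `build_nail_mesh()`) — parametric,
   watertight triangulated nail surfaces.
2. **Femur models** (`femur_model()`, `build_femur()`,
   `sample_population()`) — endosteal meshes with landmarks and a
   canonical anatomical frame; a seeded synthetic generator stands in
   for imaging data.
3. **Placement** (`entry_point()`, `place_nail()`) — the deterministic
   realization of the manufacturer rules.
4. **Metrics and statistics** (`compute_fitness()`, `build_summary()`)
   — signed penetration fields, impingement patches, the per-specimen
   fitness parameters A–H, and paired cohort comparisons.

## Coordinate conventions

All lengths are millimetres. The femur frame has its origin at the
greater-trochanter (GT) apex, +z distal along the total-least-squares
shaft axis, +y anterior, +x lateral (flipped for a left femur by the
`side` flag of the landmark file). The AP view drops y; the lateral view
drops x. Nail-local coordinates put the origin at the proximal tip, +z
toward the distal tip along the proximal segment, +x toward the lateral
face, +y anterior.

## Nail models

A nail is two straight segments joined by a circular-arc bend (default
radius 50 mm) so the swept surface stays manifold; a sharp kink would
create a non-manifold crease. The cross-section is circular, circular
with a lateral flat (PFNA-II), or trapezoidal (InterTan), morphing
linearly into the circular distal section over a taper that ends at the
bend station. The head element (helical blade or integrated twin screws)
is represented by its axis and a cylindrical envelope only: placement
and the fitness parameters depend on the axis, not on thread
micro-geometry.

Design constants that are public knowledge are fixed in the
constructors: the PFNA-II carries a 5° mediolateral bend, a 16.5 mm
proximal diameter and a flattened lateral face; the legacy PFNA a 6°
bend and 17 mm proximal diameter; the InterTan a trapezoidal proximal
section housing two cephalocervical screws. Everything else — nail
length, distal diameter, bend station, flat depth, trapezoid AP depth,
head-element geometry — is not published as a design constant, so it
lives in `inst/extdata/nail_defaults.yaml` as representative
vendor-class values (200 mm length, 10 mm distal diameter, 130° CCD,
15.5 mm trapezoid AP depth, 2 mm flat depth). Every pipeline run records
the values it used in its manifest; none of them is hard-coded in an
operation.

## Synthetic femurs

No imaging data ships with the package, so the cohort is synthetic by
construction, not by preprocessing. The endosteal canal is a
circular-section tube swept along a sagittal-plane circular arc (the
anterior bow; infinite radius = straight), with radius tapering linearly
from the trochanteric flare to the isthmus and constant beyond. The
trochanteric region is closed by a flat-topped superellipse dome
(exponent 8) whose apex *is* the GT-apex landmark — the flat top makes
the guideline entry point's AP projection coincide with the apex, as the
entry rule assumes. The femoral head is a sphere reached from the neck
take-off point along the neck axis (neck-shaft angle + anteversion); the
take-off is fixed at the canal-axis point 40 mm below the GT apex, a
documented convention that the morphometric re-estimator
(`estimate_femur_params()`) shares.

Population defaults (truncated normals, mean ± 3 sd bounds) centre on
East-Asian literature-typical values: neck-shaft angle 129° ± 5°,
anterior bow radius 900 ± 150 mm, isthmus radius 5.5 ± 0.8 mm, femur
length 400 ± 20 mm, flare radius 14 ± 1.5 mm, isthmus station 200 ± 20
mm, neck length 50 ± 5 mm, anteversion 15° ± 5°, head radius 22 ± 1.5
mm, trochanter overhang 12 ± 2 mm. These are declared assumptions — the
study cohort's morphometrics were never published — and every entry is
overridable through `population_spec()`. Sampling uses inverse-CDF
truncated normals with per-femur child seeds derived from the master
seed by counter, so femur *i* is reproducible independently of cohort
size.

What the generator does *not* emulate: elliptical canal sections,
cortical thickness, metaphyseal asymmetry, a lateralized GT apex, and
statistical shape variation beyond the ten parameters. Passing tests on
this cohort therefore validate the *pipeline mechanics* (placement
rules, signed distances, patch logic, statistics), not the clinical
magnitudes of any particular population.

## Placement

The guideline fixes the entry point (GT vertex in the AP view, the
anterior/middle-third boundary of the local trochanteric AP extent in
the lateral view) and requires the head element to pass through the
femoral head centre. After the entry point is fixed and the nail's
proximal axis is aligned with the insertion direction (the shaft axis by
default; a trochanteric approach angle is configurable because the
guidelines are silent), exactly two surgical freedoms remain: insertion
depth and axial rotation. `place_nail()` minimizes the head-centre miss
distance over those two variables — an exhaustive 1 mm × 1° grid
followed by golden-section refinement to 0.01 mm / 0.01°, with grid ties
broken toward smaller depth, then smaller rotation. The placement is
fully deterministic and rigid-equivariant.

Penetration of the cortex is *permitted* during placement: the method
exists to measure the conflict between the rule-compliant position and
the bone, so the solver never deforms the trajectory to avoid
impingement, and an infeasible head-centre constraint is reported as
non-convergence (best miss attached) rather than an exception.

## Penetration field and fitness parameters

The nail shaft surface is sampled at a target areal density (default 4
samples/mm²) and each sample gets a signed distance to the endosteal
surface: negative inside the canal volume, positive protruding into
cortex. The sign comes from ray-crossing parity on the watertight mesh;
the magnitude is the exact point-to-triangle distance (compiled, with a
z-slab spatial index). Samples within 15 mm of the entry plane are
excluded from patch extraction: the synthetic trochanteric surface is
closed, so the nail necessarily crosses it at the (in reality reamed)
entry portal.

Impingement patches are single-linkage connected components (2 mm
linkage radius) of samples deeper than the 0.1 mm threshold. The
original CAD workflow judged impingement visually; the numeric threshold
and linkage radius are explicit configuration so the binarization is
reproducible. Patch thickness is the maximum member depth (penetration
normal to the cortex), length the member station extent, location the 3D
Euclidean distance from the GT apex to the patch centroid (an
along-axis alternative would be a straightforward extension; the
straight-line distance matches how the measurement is drawn in a cut
plane). Regions are nail-relative — proximal up to the bend station plus
a 10 mm margin, distal the last quarter of the inserted length, middle
between, boundary ties going proximal — because the study's observed
hot-spot depths (about 60 mm and 155 mm below the GT apex, and the
distal tip) are findings, not definitions. Sides are 90° sectors about
the local nail axis (ties to the mediolateral sector).

The per-specimen report assembles: **A** greatest proximal impingement
thickness, **B** mean proximal patch length, **C** GT-apex distance of
the thickest proximal patch, **D** tip protrusion above the GT plane
(clamped at 0), **E** mid-shaft thickness and length, **F** GT-apex
distance mid-shaft, **G** the maximum anterior gap between nail and
inner cortex in the middle region (per-station ray cast along +y from
the nail's anterior-most surface point; a station whose anterior point
already penetrates the cortex contributes gap 0), and **H** distal patch
length. Regions without patches report `NA`, never 0 — an absent
impingement is not a zero-thickness one. When several patches share a
region, A/E/H take the maximum thickness, B/E/H lengths average over
patches, and C/F follow the thickest patch; per-specimen multi-patch
semantics had to be fixed somewhere and are recorded here.

## Cohort statistics

Both designs are fitted to every femur (paired design). Incidences are
counts of specimens with any patch in a region, compared on the 2×2
table by Pearson's chi-square *without* continuity correction when all
expected counts are ≥ 5 and by the two-sided Fisher exact test
otherwise; the variant is documented because no standard variant
reproduces the source study's printed p-values from its printed counts,
and the package is deliberately not calibrated to them. Millimetre
metrics are compared by a paired t-test on per-specimen differences
(the natural reading of a repeated-measures comparison with two
conditions), with a Wilcoxon signed-rank alternative behind
`paired_method = "wilcoxon"`. Percentages are rounded half-up to one
decimal, millimetre summaries to two, in rendered outputs only; JSON
keeps full precision. No multiplicity correction is applied across the
comparisons, matching the source analysis. Specimens with a
non-converged placement are dropped from metric summaries and counted
separately.

## Numerical choices

* Meshes are indexed triangle sets; watertightness (every edge shared by
  exactly two consistently oriented faces) is checked on construction
  and is a precondition of the signed distance.
* Ray-parity containment retries a fan of horizontal probe directions
  and tiny z-jitters so that query points lying exactly in a
  tessellation ring plane (common in constructed geometry) stay
  decidable.
* The depth/rotation objective is quadratic in depth for fixed rotation,
  so the coarse grid is evaluated exactly from three coefficient
  vectors; refinement can only improve on the grid optimum and falls
  back to it otherwise.
* Mesh resolutions (canal rings every 3 mm, 24 vertices per ring; nail
  rings every 2 mm, 32 per ring; sampling density 4/mm², 2/mm² in the
  bundled demo config) keep a full 120-femur, two-nail cohort run at
  roughly two minutes on a single core while holding the analytic-oracle
  errors (cylinder penetration, girth, volume) within the tolerances the
  tests assert.

## Known limitations

* With the default insertion direction (shaft axis) the nail trajectory
  is a straight line anchored at the entry point, so in a strongly bowed
  canal the distal nail diverges from the canal axis by nearly the full
  arc sagitta. Combined with the synthetic canal keeping its isthmus
  calibre over the whole distal shaft, mid-shaft and distal penetrations
  come out systematically deeper than cadaveric studies report, and long
  connected posterior contact zones can span the middle/distal boundary
  (a patch is assigned to one region by its centroid). The incidence
  *orderings* between designs are informative; the absolute millimetre
  magnitudes of the synthetic cohort are not calibrated to any real
  population.
* The entry point is held fixed even when unreachable in a deformed
  trochanter; the solver then reports non-convergence instead of
  emulating a surgeon's compensatory entry shift.
* Anteversion interacts with placement only through axial rotation;
  torsional bow (helical canals) is not modelled.
* Impingement thickness is measured normal to the cortex; a cut-plane
  reading can differ slightly on oblique patches.

## Reproducing a run

```{r demo, eval = FALSE}
res <- run_pipeline(demo_config(), out_dir = tempfile("femfit_demo_"))
res$summary
```

Any output directory can be regenerated byte-identically for the tables
from the `run_manifest.json` it contains (config snapshot + seed). The
full-size experiment (n = 120, both designs) is what
`scripts/acceptance.R` executes.
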