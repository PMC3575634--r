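# femfit — virtual fitting of proximal femoral intramedullary nails

`femfit` is an R package for quantifying how well cephalomedullary nail
designs fit the proximal femur. It is aimed at implant-design and
computational-anatomy work where the question is geometric, not
mechanical: if a nail is placed *exactly* by the manufacturer's rules,
where does it collide with the inner cortex, by how much, and how do two
designs compare over a cohort?

The pipeline it implements:

1. **Parametric nail models.** `make_pfna2_spec()` (5° mediolateral
   bend, 16.5 mm proximal diameter, flattened lateral face),
   `make_pfna_legacy_spec()` (6°, 17 mm, circular) and
   `make_intertan_spec()` (trapezoidal proximal section, integrated
   twin-screw corridor) build validated specs; `build_nail_mesh()`
   realizes them as watertight triangulated surfaces with an axis
   polyline and a head-element axis.
2. **Landmarked femur models.** `load_femur()` reads an endosteal
   surface (STL/PLY, mm) plus a landmark file (GT apex, head centre,
   shaft-axis points, anterior direction); `build_femur()` /
   `sample_population()` generate seeded synthetic cohorts with
   configurable anterior bow, neck-shaft angle, neck length, canal
   calibre and trochanter geometry.
3. **Rule-based placement.** `place_nail()` puts the entry point at the
   GT vertex (AP view) and the anterior-third boundary (lateral view),
   aligns the nail with the insertion direction, and solves insertion
   depth and axial rotation so the head-element axis passes through the
   femoral head centre — a deterministic grid minimization of the
   head-centre miss distance

   `min_(depth, phi)  d(head_axis(depth, phi), c_head)`

   refined to 0.01 mm / 0.01°.
4. **Fitness metrics A–H.** `compute_fitness()` samples the nail
   surface, computes signed nail-to-cortex penetration (negative inside
   the canal), extracts connected impingement patches above a 0.1 mm
   threshold, and reports per region (proximal / middle / distal):
   maximum impingement thickness, mean patch length, patch distance to
   the GT apex, tip protrusion above the GT plane, and the maximum
   anterior gap between nail and inner cortex at mid-shaft.
5. **Paired cohort statistics.** `build_summary()` aggregates paired
   per-specimen reports into incidence tables (chi-square without
   continuity correction, or Fisher's exact test when expected counts
   fall below 5) and mean ± SD metric comparisons (paired t-test, or
   Wilcoxon signed-rank behind a flag).

## Worked example

Fit a PFNA-II-like nail to one synthetic femur:

```r
library(femfit)
p    <- sample_population(population_spec(1, 42))[[1]]
f    <- build_femur(p, id = "demo_femur")
spec <- make_pfna2_spec(length = 200, distal_diameter = 10)
nail <- build_nail_mesh(spec)
pl   <- place_nail(f, nail, spec)
pl
#> <placement> depth 5.00 mm, rotation -11.74 deg, head-centre miss 0.003 mm (converged)
rep <- compute_fitness(f, nail, spec, pl)
rep
#> <fitness_report demo_femur / PFNA2>
#>   impinged: prox=FALSE mid=TRUE dist=FALSE; D=0.00 mm, G=11.84 mm
```

The placement converged: with the nail tip 5 mm below the entry plane
and an 11.7° internal rotation, the blade axis passes within 0.003 mm of
the head centre. This femur shows no proximal impingement and no tip
protrusion (`D = 0`), but the nail contacts the mid-shaft cortex
(`mid=TRUE`) and leaves an 11.8 mm anterior gap there (`G`) — the
signature of a straight trajectory in an anteriorly bowed canal.

A full paired run over the bundled demo cohort (10 femurs, seed 7, both
designs):

```r
res <- run_pipeline(demo_config(), out_dir = tempfile("femfit_demo_"))
res$summary
#> <cohort_summary> n = 10 (a = INTERTAN, b = PFNA2, 0 unconverged)
#>   proximal   a: 6 (60.0%)  b: 0 (0.0%)  fisher p=0.0108
#>   middle     a: 10 (100.0%)  b: 10 (100.0%)  chi-square p=1
#>   distal     a: 0 (0.0%)  b: 0 (0.0%)  chi-square p=1
#>   protrusion a: 0 (0.0%)  b: 4 (40.0%)  fisher p=0.0867
```

Row by row: the trapezoidal proximal section impinges proximally in 6 of
10 femurs while the flat-faced design clears all 10 (Fisher p = 0.011);
both designs contact the bowed mid-shaft in every specimen; and only the
PFNA-II-like nail ever sits proud of the trochanter tip. The output
directory holds per-case JSON reports, `summary.json` / `summary.csv`,
and a `run_manifest.json` from which the run can be regenerated
byte-identically.

A thin command-line wrapper over the same functions ships at
`inst/cli/femfit.R` (`simulate`, `fit`, `run` subcommands).

## Scope notes

The synthetic generator's defaults are declared, overridable assumptions
about East-Asian femoral morphology (the methods vignette,
`vignettes/virtual-nail-fitting.Rmd`, documents every default, the
placement conventions, and the known limitations). CT segmentation,
reaming/fracture simulation, thread geometry and mechanical (FEA)
analysis are out of scope.
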