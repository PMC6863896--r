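# octa3d

Volumetric analysis of OCT angiography (OCTA) cubes for **type 3 macular
neovascularization (MNV)** — intraretinal neovascular lesions of
age-related macular degeneration that rise from the deep vascular
complex (DVC) and grow downward toward the retinal pigment epithelium
(RPE) and the sub-RPE space. Conventional OCTA review collapses the flow
volume into 2D en face slabs, which hides exactly what matters for these
vertically developing lesions: overlapping lesions fuse into one blob,
and 3D shape, inclination and sub-RPE contact are invisible. `octa3d`
analyzes the volume as a volume and keeps the 2D slab count as the
comparator arm.

For retina researchers and imaging-pipeline developers, the package
provides:

* **I/O** — headerless 8-bit raw volumes (axial-first, `(z, x, y)`) and
  multi-page TIFF stacks, with axis reorientation and per-A-scan layer
  surfaces (DVC outer boundary, RPE, Bruch's membrane) as CSV.
* **Volumetric projection-artifact removal** — decorrelation tails are
  removed by serial correction of thin, overlapping axial subvolumes at
  increasing depth. Inside window `[z0, z0+h)` the projected component is
  `P(z) = α · max(refl(z), ε)/255 · A(z)`, where `A(z)` is the
  exponentially decayed (constant `τ`) accumulation of the
  already-corrected flow above; overlapping windows average their
  corrections. A single-reference slab-style remover is included as the
  baseline.
* **3D lesion morphometry** — 26-connected detection between the DVC
  boundary and Bruch's membrane, origin-seeded splitting of merged
  lesion complexes, centerline skeletons, saccular/filiform
  classification by the elongation `E = L/(2·r̄)` (filiform iff
  `E ≥ 3`), inclination to the local Bruch's-membrane plane, and sub-RPE
  contact flags.
* **Rotational rendering** — spacing-aware rotated maximum-intensity
  projections, flow-only or merged (structure in white, flow in
  magenta), exported as PNG frame series.
* **Cohort summaries** — per-eye counts, mean ± SD (n−1), range, shape
  percentages, type 1 MNV co-presence, and the 2D-vs-3D comparison.
* **A synthetic phantom** — a 3 × 3 mm macular cube with layered retina,
  two plexuses, closed-form projection tails, optional pigment
  epithelial detachment, and planted lesions of known position, shape
  class, inclination and sub-RPE contact. All quantitative claims are
  validated against this ground truth.

## Worked example

Cohort arithmetic from raw per-eye counts (here: the published totals of
a 15-eye cohort — 22 lesions on 2D en face images, 35 on 3D of which 9
saccular, 7 eyes with associated type 1 MNV, 19 ICGA lesions):

```r
library(octa3d)
shapes     <- c(rep("saccular", 9), rep("filiform", 26))
counts_3d  <- c(5, 4, 4, 3, 3, 3, 2, 2, 2, 2, 1, 1, 1, 1, 1)
lesions_3d <- split(shapes, rep(seq_along(counts_3d), counts_3d))
s <- summarize_lesions(
  lesions_2d = c(4, 3, 2, 2, 2, 2, 1, 1, 1, 1, 1, 1, 1, 0, 0),
  lesions_3d = lesions_3d,
  t1_mnv     = rep(c(TRUE, FALSE), c(7, 8)),
  icga       = c(3, 2, 2, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0))
print(s)
#> Eyes: 15
#> Type 1 MNV co-presence: 7 (46.7%)
#> Lesions on 2D en face OCTA: 22 [mean 1.5 +/- 1.1, range 0.0-4.0]
#> Lesions on 3D OCTA: 35 [mean 2.3 +/- 1.3, range 1.0-5.0]
#>   saccular 9 (25.7%), filiform 26 (74.3%)
#> Lesions on ICGA: 19 [mean 1.3 +/- 0.7]
compare_2d_3d(s)$difference
#> [1] 13
```

The shape percentages (25.7% / 74.3%), the type 1 MNV co-presence
(46.7%) and the mean ICGA lesion count per eye (1.3) are recomputed from
the raw counts; the per-eye mean/SD/range lines describe the particular
per-eye split used here, which is one consistent realization of the
totals.

End-to-end phantom analysis — generate a 150 × 150 × 160 cube with three
planted lesions, remove projection tails, detect and characterize in 3D,
and count the 2D comparator:

```r
spec <- random_phantom_spec(n_lesions = 3, seed = 11)
ph   <- generate_phantom(spec)
res  <- analyze_volume(ph$flow, ph$struct, ph$truth$surfaces)
res$n_2d; res$n_3d
#> [1] 3
#> [1] 3
res$table[, c("shape_class", "elongation", "inclination_deg", "reaches_sub_rpe")]
#>  shape_class elongation inclination_deg reaches_sub_rpe
#>     filiform       4.97            33.1           FALSE
#>     filiform       4.76            54.7            TRUE
#>     filiform       4.44            54.6            TRUE
artifact_metrics(ph$flow, res$corrected, ph$truth)
#> $suppression 0.978  $preservation 0.973  $dice 0.987
```

So 97.8% of the planted tail energy was removed while 97.3% of true
flow energy survived; all three lesions were recovered with their
shapes, inclinations (planted: 32.5°, 56.2°, 55.7°) and sub-RPE flags.
Rotational frames: `render_rotation_series(res$corrected, ph$struct,
axis = "y", n_frames = 36, out_dir = "frames", mode = "merged")`.

A command-line wrapper ships in `inst/cli/octa3d`
(`octa3d phantom | par | enface | detect | render`); see its header for
usage.

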