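---
title: "Volumetric OCTA analysis of type 3 macular neovascularization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric OCTA analysis of type 3 macular neovascularization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octa3d)
```

## The problem

Type 3 macular neovascularization (MNV) — historically "retinal
angiomatous proliferation" — is an intraretinal neovascular lesion of
age-related macular degeneration that originates in the deep vascular
complex (DVC) and grows downward through the outer retina toward the
retinal pigment epithelium (RPE) and the sub-RPE space. Standard OCT
angiography (OCTA) review collapses the flow volume into 2D en face slab
projections, which is a poor match for a lesion that develops mostly
*vertically*: separate lesions whose footprints overlap in projection
fuse into one blob, and depth structure (shape, inclination, sub-RPE
contact) is lost. `octa3d` implements the volumetric alternative: remove
projection artifacts in 3D, detect and characterize lesions as 3D
objects, and render rotational maximum-intensity projections — with a 2D
slab-counting arm retained as the comparator.

Because no patient volumes are distributed, a synthetic phantom with
planted lesions of known geometry is a first-class module: every
quantitative claim the package makes is validated against phantom ground
truth.

## Volume conventions

Volumes are 8-bit arrays in canonical axis order `(z, x, y)`, axial index
first and increasing with depth; headerless raw exports store the axial
index fastest. Voxel spacing defaults to `(dz, dx, dy) = (2, 10, 10)` um
for a 3 x 3 mm, 300 x 300 A-scan macular cube. The axial pixel count and
sampling of exported cubes is instrument configuration, so it is a
parameter everywhere; no routine assumes isotropy — lengths and angles
are always computed in micrometers through the spacing. Indices are
1-based throughout, R's native convention, and layer surfaces (DVC outer
boundary, RPE, Bruch's membrane (BM)) are stored as fractional 1-based
voxel depths per A-scan. Slab bounds are half-open `[top, bottom)`.
Surfaces are *inputs*: segmentation of structural OCT is out of scope.

## The projection-tail model

The defining OCTA artifact is the decorrelation tail: light passing
through flowing blood decorrelates, so bright *posterior* structures
(most visibly the RPE) show spurious flow beneath true vessels. The
phantom generates tails in a closed form chosen so that independent
oracles can evaluate it directly:

$$\mathrm{tail}(z) \;=\; \alpha \cdot \frac{\mathrm{refl}(z)}{255}
  \cdot \sum_{z' < z} \mathrm{flow}(z')\, e^{-(z - z')\,dz/\tau},$$

applied only where reflectivity exceeds the background level. Two
parameters matter:

* `alpha` (dimensionless, default **0.08**) — tail amplitude. The value
  is constrained by the 8-bit dynamic range: with 2 um axial sampling the
  decayed accumulation above a voxel near the bottom of a thick vessel or
  lesion bulb reaches a few thousand intensity-units, and amplitudes much
  above ~0.1 push `signal + tail` past 255. Clipping would make the
  artifact physically unremovable (information is destroyed), so the
  default keeps the worst-case column just inside the range while still
  producing conspicuous tails (~40-120 gray levels on the RPE beneath
  vessels).
* `tau` (um, default **150**) — decay constant. Tails must persist from
  the inner-retinal plexuses (60-145 um depth) onto the RPE (~230 um) to
  reproduce the artifact pattern seen clinically; decay constants much
  below ~100 um would extinguish them before the RPE.

For the same reason, planted lesions default to intensity 90 versus 200
for plexus vessels: capillary tufts carry slower flow (lower
decorrelation) than parent vessels, and the lower value keeps the
bulb-on-RPE worst case unclipped.

## Volumetric projection removal

The removal algorithm processes thin axial windows `[z0, z0 + h)` at
strides `s < h`, at increasing depth, so every interior voxel is visited
in `ceiling(h/s)` consecutive overlapping steps (exactly that many when
`s` divides `h`, the default `h = 8, s = 4`). Within a window the
projected component is estimated as
`P(z) = alpha * max(refl(z), eps)/255 * A(z)`, with `A(z)` the decayed
accumulation of the *already corrected* flow above the window plus the
partially corrected flow inside it, and subtracted with clamping at
zero. Overlapping windows contribute the arithmetic mean of their
corrections — a deterministic, order-independent combination. Because
windows above are finalized before deeper windows run, the procedure is
depth-causal: corrections never propagate anteriorly.

The estimator form mirrors the generative tail model; that symmetry is a
design choice, made so that matched parameters give a sharp ground-truth
test of the *serial windowed machinery* itself (suppression of true-tail
energy with preservation of true flow), rather than confounding it with
model mismatch. A deliberately single-reference variant
(`remove_projection_slab`), which accumulates from the raw volume in one
pass, is included as the baseline that volumetric serial correction
improves upon: its reference still contains the tails, so deep layers
are over-corrected. `fit_tail_params()` offers a pragmatic per-volume
calibration of `alpha`/`tau`: in the structurally bright, anatomically
avascular band just below BM the observed flow is pure artifact, and
the predicted tail is linear in `alpha`, so the amplitude is a
closed-form least-squares coefficient per candidate `tau` (the
candidate with the smallest residual wins). The reference accumulation
is the raw, tail-containing flow, which biases the amplitude slightly
low; it is a heuristic, not an identifiable fit, and phantom work uses
matched parameters explicitly. (An earlier objective — minimizing
residual band energy after correction — is degenerate under
zero-clamping: over-subtraction is free, so larger amplitudes always
win.)

On 150 x 150 x 160 phantoms across seeds, matched-parameter removal
suppresses ~98% of tail energy while preserving ~97% of true-flow
energy (the residual loss is concentrated where vessel self-tails
saturate the 8-bit range). `alpha = 0` is an exact passthrough by
construction.

## 3D lesion detection and morphometry

Detection restricts flow to the anatomy where type 3 lesions live —
strictly below the DVC outer boundary, down to and including BM —
thresholds it (default 60), and labels 26-connected components
(26-connectivity favors capturing thin oblique tubes; the 2D comparator
uses 4-connectivity to stay conservative). Components must contain at
least `min_voxels` (20), contact the DVC boundary within one voxel, and
extend at least 20 um below it; the depth requirement rejects plexus
vessels grazing the boundary.

**Origin splitting.** A component with several distinct DVC contact
clusters is the configuration where separate intraretinal lesions join
one vascular trunk. Counting follows origins: the component is
partitioned by anisotropic in-mask Dijkstra from the contact clusters,
yielding one record per origin with a shared `merge_group`. The origin
voxel is the contact voxel of minimum depth, ties broken by lowest x
then y. This origin-seeded rule is our operationalization of "distinct
lesions that merge"; human graders' criteria are unknown.

**Centerline.** Within each record, geodesic-distance shells from the
origin are reduced to their sub-voxel voxel centroids, lightly smoothed.
This traces the axis of a tube and the axis of symmetry of a bulb. A raw
shortest-path backtrace was rejected: on the strongly anisotropic
lattice it wanders off-center among near-tie paths, biasing both the
radius profile and the fitted axis; snapping centroids to voxel centers
re-introduces +-half-voxel lateral jitter that tilts short steep axes.
Skeleton length is the smoothed polyline length; the radius profile is
the physical distance from each skeleton sample to the nearest
background voxel, trimmed 15% at each end (path tips touch the mask
boundary, so their radii are boundary artifacts).

**Shape.** The saccular/filiform dichotomy is operationalized by the
elongation `E = L / (2 * rbar)`; filiform iff `E >= 3`. An isolated
sphere measures about 2 (path through the diameter over mean chord
radius), long tubes measure well above 5; on phantoms planted shapes
separate as ~1.5-2.0 (saccular) versus ~4.5-13 (filiform), so the
critical value 3 sits in the gap. It is configuration (`e_crit`), not a
fitted constant.

**Orientation.** The principal axis is the first principal component of
the physical skeleton coordinates, oriented downward; the reference
plane is the least-squares plane of the BM surface in a 200 um lateral
window around the origin (the xy-plane through the lesion origin is
taken parallel to it). Inclination is the angle between axis and plane
in `[0, 90]`; axis angles to the Cartesian axes come from direction
cosines folded to `[0, 90]`. A degenerate PCA falls back to the
endpoint-to-endpoint vector and is flagged. On phantoms the mean
absolute inclination error is ~2-4 degrees; the worst cases are
near-vertical saccular lesions, whose total lateral excursion (~10 um)
falls below one lateral voxel — a sampling limit, not an estimator
defect.

**Sub-RPE contact** is purely geometric: any mask voxel at or below the
RPE surface at its A-scan. The instrument cannot distinguish absent flow
from flow below the slowest detectable flow, so a FALSE flag means "no
detected connection", not proof of anatomical disconnection.

## The 2D comparator and the undercount mechanism

`enface_projection` implements slab collapse with `max`/`sum`/`mean`
reducers. Named slabs are declared configuration, not vendor-faithful
definitions (those are not public): "outer retina" is
`[DVC + 10 um, RPE)`; "RPE fit" runs from a box-smoothed RPE surface to
BM inclusive. 2D counting thresholds the slab image (Otsu by default,
fixed thresholds in all phantom work for determinism) and counts
4-connected components of at least `min_area` pixels.

The undercount mechanism is reproduced deterministically: phantoms with
converging lesions that share a trunk overlap in en face projection and
count as one 2D blob but two (or three) 3D records, while laterally
separated lesions give equal counts. The 3D count is never below the 2D
count on any phantom.

## Rotational rendering

`render_frame` rotates the volume rigidly about its physical centroid by
`(theta_x, theta_y, theta_z)` — applied in that fixed order — with
trilinear interpolation in physical coordinates (so anisotropic voxels
rotate without distortion), then max-projects along the axial view axis.
MIP was chosen over alpha-compositing ray casting: it matches the
high-flow-on-dark appearance of OCTA renderings, is deterministic, and
needs no transfer function. The sampling grid is the input grid
zero-padded in whole voxels to cover the rotation sphere, which makes
frame size angle-independent and — because padded grid points coincide
with voxel centers — makes the identity rotation *exactly* equal to the
plain axial MIP (zero border aside). Merged mode composites the
structural MIP in gray and the flow MIP in magenta by per-pixel maximum.
`render_rotation_series` writes `frame_0000.png, ...` at equal angular
steps over a full turn.

## Cohort summary

`summarize_lesions` reproduces clinical-table arithmetic: totals,
per-eye mean, sample standard deviation (n-1 denominator; the convention
is not stated in such tables, so the choice is flagged in the output
metadata and a single eye reports SD 0 with `sd_defined = FALSE`),
range, shape percentages, and type 1 MNV co-presence. Percentages are
rounded half away from zero to one decimal, matching the printed style
of clinical tables. With the published raw counts (15 eyes; 22 lesions
on 2D and 35 on 3D, of which 9 saccular; 7 eyes with type 1 MNV; 19
ICGA lesions) it reproduces the printed derived cells exactly: 25.7% /
74.3% / 46.7%, mean 1.3 ICGA lesions per eye, and a 2D-to-3D detection
difference of 13.

## What the phantom does and does not emulate

The phantom renders reflectivity bands (RPE brightest), two straight
plexuses, lesions as tubes (filiform) or stalk-plus-bulb (saccular)
growing downward from the DVC at planted inclinations, an optional PED
dome lifting the RPE, the closed-form tails above, multiplicative
speckle (SD 0.05) on signal voxels and sparse background noise (rate
0.001). Default problem size is the full-protocol lateral grid scaled to
150 x 150 A-scans with 160 axial samples, which keeps a five-seed
validation sweep within minutes on one CPU; unit tests use a 100 x 100
lateral grid with identical anatomy.

It does **not** emulate optics-accurate speckle statistics, eye motion
or bulk-motion line artifacts, curved or branching lesions, vessel
caliber variation, or segmentation error in the input surfaces. Passing
the phantom suite therefore demonstrates correctness of the geometry,
artifact-removal machinery and morphometry under known ground truth — it
does not certify performance on patient volumes, where segmentation
quality and motion artifacts dominate.

## Numerical choices and degenerate inputs

* Thresholds: detection 60/255 on corrected flow, configurable; 2D
  counting reuses the 3D threshold in phantom work, Otsu otherwise.
* Reflectivity floor `eps = 1` prevents a zero structural gate from
  hiding tails in locally dark tissue.
* Corrected volumes are requantized to uint8 with rounding; with
  clamping enabled the output is additionally capped voxelwise by the
  input, so `corrected <= raw` holds exactly after rounding.
* Empty detection zones return an empty record list, not an error; a
  single-voxel lesion cannot be classified and raises an error naming
  the degeneracy; collinear skeletons fall back to the endpoint vector,
  flagged `degenerate_axis`.
* All phantom randomness flows from one integer seed; the global RNG
  state is saved and restored around generation.

## Known limitations

Near-vertical saccular lesions carry inclination errors up to ~15
degrees at the default 10 um lateral sampling (lateral excursion below
one voxel). The trunk of a merged lesion group is attributed to one
member record by geodesic proximity, which is arbitrary at the junction.
The elongation statistic assumes a single dominant path; a lesion with
several comparable branches from one origin is summarized by its longest
branch. The tail model and its removal share a functional form by
design; on patient data the vendor artifact differs and `alpha`/`tau`
would need the calibration heuristic rather than matched values.
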