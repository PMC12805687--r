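---
title: "3D follicle-reserve morphometry and virtual histology: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D follicle-reserve morphometry and virtual histology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

The ovarian reserve — the pool of primordial follicles in the ovarian
cortex — is assessed clinically from a handful of histological sections of
a small cortical biopsy. That estimate drives decisions in fertility
preservation (ovarian tissue cryopreservation, OTC), yet it rests on a
sparse 2D sample of a heterogeneous 3D tissue. Micro-CT-scale imaging of
iodine-stained cortex makes full-volume 3D counts possible: oocytes appear
as hypodense spheres of roughly 30–40 µm, the surface epithelium as a
hyperdense shell, and an instance segmentation of the volume yields every
oocyte's position and size.

`follimetry` implements the quantitative side of that workflow as tested,
reusable code:

1. **instances** — from a binary oocyte mask to clean instances
   (noise removal, vessel filtering, watershed separation of touching
   oocytes) with Dice/precision/recall scoring;
2. **morpho3d** — cortex delineation (tissue within 1 mm of the surface
   epithelium), per-oocyte depth, 40 µm neighbor counts, volumetric
   density, cluster flags;
3. **virtslice** — virtual histology: sectioning a known 3D population
   into 4 µm slabs, counting profiles, and applying a
   Schmidt/Abercrombie-type duplicate-count correction, with sweeps over
   sampling interval and starting offset;
4. **phantom** — a cluster point-process generator of synthetic cortical
   volumes with known ground truth, which supplies the study conditions
   for everything above.

Raw patient volumes of this kind are not publicly available, so the
phantom is not a convenience but the package's evidential basis: every
claim the analysis scripts and tests make is a claim about recovery of a
known synthetic truth, plus the direction of the contrasts observed in
real pediatric vs adult tissue.

# The phantom

## Point process

Oocyte centers follow a Thomas-type cluster process: cluster parents are
Poisson with intensity $\lambda$ per mm³ of cortex, each parent spawns a
Poisson($\mu$) number of offspring displaced isotropically in 3D by a
Gaussian with standard deviation $\sigma_c$. Primordial follicles sit in
nests, and the defining empirical signature of pediatric cortex — a median
of ~6 neighbors within 40 µm — can only come from compact 3D clusters:
at realistic densities, the "background" contribution of unclustered
neighbors is below one.

Two design choices deserve explanation:

* **Depth via the parent, not the offspring.** The depth law (how deep
  below the epithelium centers sit) is imposed on the *parent*; offspring
  scatter around it in all three axes. Re-drawing each offspring's depth
  independently would destroy within-cluster proximity along the depth
  axis and cap the achievable neighbor counts far below what real
  pediatric tissue shows. The price is that the marginal depth
  distribution is the depth law smeared by $\sigma_c$; since
  $\sigma_c$ (11–13 µm) is small against the depth-law spread
  (lognormal $\sigma = 0.6$ around medians of 134–370 µm), the smearing is
  invisible to a Kolmogorov–Smirnov test at $n = 2000$ ($\alpha = 0.01$),
  which the test suite checks.
* **Soft-shell hard core.** A minimum surface-to-surface separation
  `min_gap` is enforced by rejection. Poisson cluster sizes have tails
  that occasionally exceed what a fixed-σ Gaussian nest can pack, so a
  proposal that keeps failing widens its scatter by a factor
  $(1 + \text{tries}/150)$ — a crowded nest pushes late arrivals outward.
  This makes every reasonable specification feasible while a global
  budget (500 proposals per target oocyte) still turns truly infeasible
  densities into an explicit `"packing infeasible"` error, never a
  silently under-filled volume.

Diameters are lognormal (σ = 0 gives a monodisperse population). Depth
laws available: lognormal (median, σ), exponential (scale), and uniform
(min, max); the uniform law exists to build homogeneous phantoms whose
oocytes all lie inside the cortex, the cleanest setting for estimator
validation. Rasterization is voxel-center-in-sphere at 2.28 µm isotropic
voxels, so a sphere's voxel volume deviates from $\pi D^3/6$ by
$O(\text{voxel}/D)$ — under 5 % for 30 µm oocytes, which is the tolerance
the tests use for equivalent diameters.

## Calibrated presets

`phantom_preset()` freezes two regimes, calibrated once by simulation
(10 seeds at the default 400×400×600-voxel grid) against the published
contrast between pediatric and adult cortex:

| parameter | pediatric | adult |
|---|---|---|
| parents λ (per mm³ cortex) | 360 | 97 |
| mean cluster size μ | 9 | 4 |
| cluster σ (µm) | 13 | 11.5 |
| min_gap (µm) | −10 | −4 |
| depth law (µm) | lognormal(134, 0.6) | lognormal(370.2, 0.6) |
| diameters (µm) | lognormal(31, 0.07) | lognormal(34, 0.09) |
| realized median depth (µm) | ≈ 135 | ≈ 350 |
| realized median neighbors | ≈ 6 | ≈ 2 |
| realized density (per mm³) | ≈ 3200 | ≈ 390 |

The pediatric depth-law median is set slightly below the target because
containment (a sphere must clear the epithelium by its radius) and the
cluster smear shift the realized median up a few percent. The negative
`min_gap` values encode slight interpenetration: follicle nests abut, and
a median of 6 neighbors within 40 µm for ~31 µm oocytes is geometrically
impossible with fully separated spheres of that size sampled by rejection.
Label volumes remain disjoint regardless (first-come rasterization).

What the phantom does **not** model: non-spherical oocytes, vascular
trees, anisotropic voxels, scanner physics (beam hardening, rings),
curvature of real fragments (the default surface is a plane; a spherical
cap is available). Consequently, passing tests show that the *pipeline*
recovers known truth and reproduces the direction and rough magnitude of
the published contrasts — not that it would segment a real scan; the
thresholding stand-in for segmentation is deliberately simple and is
validated only on rendered phantoms.

# Morphometrics

The cortex is tissue within `cortex_depth` (default 1000 µm) of the
epithelium under the exact Euclidean distance transform, computed in
physical units by a separable Felzenszwalb–Huttenlocher transform (exact,
not chamfer). Per-oocyte depth interpolates the distance field
trilinearly at the centroid, giving sub-voxel values; a boundary
convention (centroid depth minus radius, clamped at zero) is available by
flag since published minimum depths below the voxel size suggest surface
rather than centroid measurement in the original workflow. Neighbor
counts use centroid-to-centroid distance with an inclusive 40 µm boundary
— the radius reported as the limit of follicular neighbor effects — via
grid binning that the tests pin to the quadratic definition. Density is
the count of oocytes whose centroid voxel lies in the cortex mask divided
by cortical volume; an oocyte straddling the 1 mm shell counts iff its
centroid is inside.

A sample whose epithelium is not visible cannot support depth
measurements; `run_pipeline()` then warns, skips depths, and divides by
the tissue volume instead.

# Instance extraction

Connected components (26-connectivity default) are split where the
interior distance transform holds two or more local maxima at least
`split_min_distance = 15 µm` apart, by marker-controlled watershed on the
negated distance transform. Determinism is explicit: candidate maxima are
collapsed per connected plateau (a tube's ridge is one candidate, which
is also what keeps vessels from being chopped into sphere-sized pieces),
ranked by distance value with lexicographic index tie-break, and greedily
thinned to the minimum spacing within each component. Instances smaller
than the volume of a 10 µm sphere (≈ 524 µm³) are dropped as noise;
instances with principal-axis elongation above 4 are dropped as vessel
fragments (tubes being the alternative hypothesis to spheres). The
original workflow performed these steps interactively without published
thresholds; the defaults here are conservative for 30–40 µm oocytes and
all are exposed. An optional pre-labeling erosion (`erode_voxels`)
emulates the deliberate one-pixel shrinkage sometimes used to prevent
instance merging, at the cost of recall.

# Virtual histology and the corrected estimator

Sections are half-open slabs $[(s-1)t, st)$ of thickness $t = 4$ µm,
1-based, tiling the chosen axis; the clinical five-section design is
sections 10, 20, 30, 40, 50 (40 µm spacing). A sphere appears in a
section iff its extent overlaps the slab with positive measure —
boundary-grazing spheres are counted once, never twice — and its largest
in-slab circle diameter clears a visibility floor (default 5 µm,
modeling undetectable polar caps; 0 for pure geometry). The profile
diameter is the full diameter if the equator lies in the slab, else
$2\sqrt{(D/2)^2 - \delta^2}$ at the nearest slab face. Slab areas come
from the 3D cortex mask restricted to the slab, which removes the
orientation ambiguity that plagues real sections.

**Sectioning axis.** Histological sections of a cortical strip are cut
across the strip: the epithelium is an edge *within* the section plane
and each section spans the full depth range. For phantoms whose
epithelium is the z = 0 plane the analyses therefore section along x.
Sectioning parallel to the surface would make the five-section design
sample only the shallow 36–200 µm band and inflate pediatric estimates
several-fold — an artifact of geometry, not of sparse sampling.

With $P$ profiles over the analyzed sections, sampling interval $k$, and
$\bar{D}$ the mean diameter of the largest 10 % of sectioned oocytes
(per-oocyte maximum profile diameter, deduplicated across sections — the
convention named "largest 10 % of oocytes"; a pooled-profile variant is
available by flag), the corrected count and examined volume are

$$\hat{N} = \frac{P\,k\,t}{t + \bar{D}}, \qquad
  V_{\text{ext}} = \textstyle\sum_i A_i \, k \, t,$$

so that corrected density $= \hat{N}/V_{\text{ext}}$ and uncorrected
density $= P / (\sum_i A_i\, t)$ obey the exact identity
$\text{corrected} = \text{uncorrected} \times t/(t+\bar{D})$. The
original correction of this family is cited in the source literature but
not reprinted; this form reproduces every behavior reported for it: at
$k = 1$ the uncorrected estimate overshoots truth by $(D+t)/t \approx
10$ for 36 µm oocytes in 4 µm sections; the corrected estimate is
unbiased for monodisperse spheres (each sphere yields $(D+t)/t$ profiles
in expectation, each corrected by $t/(t+D)$); and with right-skewed
diameters $\bar{D}$ overestimates the typical diameter, so the corrected
density lands *below* the 3D truth — the overcorrection the full-volume
comparison exposes (≈ −11 % on the pediatric preset). $V_\text{ext}$
extrapolates each analyzed section over its sampling period $k\,t$; for
the five-section design this reads the series as representative of its
local span, the convention under which the estimator remains a density.

Degenerate inputs are defined, not errors: zero profiles give zero
densities with $\bar{D}$ absent; a zero-area section set is an error; a
single feasible offset yields a coefficient of variation of 0.

# Group statistics

Pediatric vs adult contrasts use the two-tailed Mann–Whitney rank-sum
test: exact when $n_1 n_2 \le 400$ without ties, normal approximation
with continuity and tie correction otherwise (the variant choice is not
recorded in the source workflow; exact-when-feasible is the conservative
default). No multiple-testing adjustment is applied, matching the
original analysis. The test suite pins the implementation to exhaustive
enumeration over all group assignments for pools of up to 8 values.

# Problem sizes and numerical choices

The analysis drivers and test suite run phantoms at a reduced lateral
footprint (250×250×500 voxels ≈ 0.57×0.57×1.14 mm) with 5–10 seeds per
condition; the acceptance script uses the full default grid
(400×400×600, ≈ 0.91×0.91×1.37 mm, ~2700 pediatric oocytes) with 10
seeds. These sizes were chosen so that a complete run stays in the
minutes range on one CPU while keeping ≥ 500–2000 oocytes in every
estimate, and they are stated here because medians of integer neighbor
counts and stability horizons are discrete quantities whose seed-to-seed
wobble shrinks with population size. Grid geometry (masks, distance
field) is seed-independent for planar phantoms and is built once per
footprint.

Tie-breaking is deterministic everywhere: watershed flooding pops the
highest distance value with the smallest linear index first; marker
suppression orders by (component, −distance, index); phantom generation
consumes a single seeded RNG stream, and identical (spec, seed) pairs
reproduce bit-identical volumes and tables.

# Known limitations

* The correction formula is a reconstruction from reported behavior, not
  a transcription of the original (unpublished) variant.
* Whether depth and the 40 µm neighborhood were measured from centroids
  or follicle surfaces in the original workflow is unstated; centroid is
  the default here, the boundary variant a flag.
* The five-section extrapolation convention (per-section × $k t$) is one
  of at least two defensible readings of the clinical procedure.
* Preset calibration targets population medians; it does not claim to
  reproduce patient-level variability, age trends within regimes, or
  absolute densities beyond the stated ~8-fold regime contrast.
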