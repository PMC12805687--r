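# follimetry

3D morphometry of the ovarian follicle reserve, and virtual histology to
test when sparse 2D sampling can stand in for full-volume counts.

## The problem

The number and placement of primordial follicles in the ovarian cortex is
the quantity that fertility-preservation decisions (ovarian tissue
cryopreservation) rest on. Clinically it is estimated by counting oocyte
profiles in a few histological sections of a small biopsy. Micro-CT-scale
imaging of stained cortex gives the full 3D picture instead: every oocyte
(a hypodense ~30–40 µm sphere) with its position relative to the surface
epithelium. That raises two questions this package answers with code:

1. **What does the 3D reserve look like?** Oocyte density per mm³ of
   cortex (tissue within 1 mm of the surface epithelium), per-oocyte
   depth below the epithelium, and local clustering (neighbors within
   40 µm).
2. **How good is the 2D shortcut?** Simulate histology on a population
   with known ground truth — 4 µm virtual sections, every 10th analyzed,
   or only five sections — and compare the corrected density estimate

   $$\hat N = \frac{P\,k\,t}{t+\bar D}, \qquad
     \widehat{\mathrm{density}} = \hat N \Big/ \sum_i A_i\,k\,t$$

   (P profiles, interval k, thickness t, $\bar D$ the mean diameter of
   the largest 10 % of sectioned oocytes — a Schmidt/Abercrombie-type
   duplicate-count correction) against the true 3D density.

Because labeled patient volumes are not publicly available, the package
ships a cluster point-process **phantom generator** (Thomas-type nests,
depth-law placement under a synthetic epithelium, lognormal diameters,
hard-core packing, sphere rasterization) with calibrated pediatric-like
(dense, shallow, clustered) and adult-like (sparse, deep, dispersed)
presets. All validation is recovery of known synthetic truth.

## Worked example

```r
library(follimetry)

spec  <- phantom_preset("pediatric", dims = c(250L, 250L, 500L), seed = 1)
truth <- generate_phantom(spec, rasterize = FALSE)
geom  <- build_cortex(truth$epithelium_mask, truth$tissue_mask,
                      spec$voxel_size)
oo    <- neighbor_counts(oocyte_depths(truth$oocytes, geom))

median(oo$depth_um)        # 130.1  -- µm below the surface epithelium
median(oo$neighbor_count)  # 6      -- oocytes within 40 µm
density_3d(oo, geom)       # 3122.1 -- oocytes per mm^3 of cortex

compare_strategies(oo, geom, axis = "x")
#>         strategy density_per_mm3   rel_error
#> 1     density_3d        3122.129  0.00000000
#> 2 every_kth_full        2921.489 -0.06426383
#> 3  five_sections        3418.982  0.09508048

sw <- interval_sweep(oo, geom, k_range = c(1, 2, 5, 10, 25, 50), axis = "x")
sw[, c("k", "P", "density_corrected", "density_uncorrected", "rel_dev")]
#>    k    P density_corrected density_uncorrected rel_dev
#> 1  1 8811              2788               27252 0.00000
#> 2  2 4391              2781               27162 0.00234
#> 3  5 1744              2735               26412 0.01908
#> 4 10  863              2671               25268 0.04213
#> 5 25  320              2488               23424 0.10779
#> 6 50  120              1881               17568 0.32550
stability_horizon(sw)      # 25
```

Reading the output: uncorrected profile counting (27 252/mm³) overshoots
the true density ~9-fold because a 31 µm oocyte spans ~9 consecutive 4 µm
sections; the correction brings it to 2 788/mm³, slightly *below* truth
because $\bar D$ comes from the largest oocytes (the overcorrection a
full-volume comparison exposes). Estimates stay within 20 % of the
all-sections value through interval 25 on this dense homogeneous-regime
phantom, and every-10th sampling lands within ~6 % of the 3D density.
Sections run along x — across the cortex, perpendicular to the
epithelium, as a real histology block is cut.

The same contrast in the adult-like regime (`phantom_preset("adult")`)
shows why sparse sampling fails there: five-section estimates scatter
several-fold around the 3D truth (see `analysis/03_virtual_histology.R`).

## Analysis workflow

Numbered drivers under `analysis/` rebuild the full study on synthetic
cohorts and write tables under `results/`:

| script | what it does |
|---|---|
| `01_phantoms.R` | generates 5 pediatric + 5 adult phantoms, cohort summary |
| `02_morphometry.R` | depths, neighbor counts, densities, Mann–Whitney group tests |
| `03_virtual_histology.R` | 3D vs every-10th vs five-section strategies, offset sweeps |
| `04_interval_stability.R` | corrected-density drift across sectioning intervals |

Run them in order with `Rscript analysis/01_phantoms.R` etc.; the whole
sequence takes a few minutes on one CPU. `run_pipeline()` exposes the same
chain (phantom/volumes → segmentation → instances → cortex → morphometry
→ virtual histology) behind a single YAML/JSON config.

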