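# 3D morphometrics: cortex delineation by Euclidean distance from the
# surface epithelium, per-oocyte depth, fixed-radius neighbor counts,
# volumetric density, and cluster flags.

#' Delineate the ovarian cortex from the surface epithelium
#'
#' Computes the exact Euclidean distance transform from the epithelium
#' (physical units) and defines the cortex as tissue within `cortex_depth`
#' of it — the standard "1 mm below the surface epithelium" convention.
#'
#' @param epithelium_mask logical array of epithelium voxels; must be
#'   nonempty (a sample without a visible epithelium cannot support depth
#'   measurements — handle it by computing densities over the tissue mask
#'   instead, see [run_pipeline()]).
#' @param tissue_mask logical array of tissue voxels (same shape).
#' @param voxel_size voxel size, micrometres.
#' @param cortex_depth cortical depth, micrometres (default 1000); `Inf`
#'   makes the cortex the whole tissue mask.
#' @return An object of class `cortex_geometry`: `distance_field` (um),
#'   `cortex_mask`, `cortex_depth`, `voxel_size`, `cortical_volume_mm3`,
#'   and `layer_volume_um3` (cortex volume per z layer, used by the
#'   virtual-sectioning module).
#' @export
build_cortex <- function(epithelium_mask, tissue_mask, voxel_size,
                         cortex_depth = 1000) {
  check_dim3(epithelium_mask, "epithelium_mask")
  check_dim3(tissue_mask, "tissue_mask")
  if (!identical(dim(epithelium_mask), dim(tissue_mask)))
    stopf("mask shapes differ")
  if (!any(epithelium_mask))
    stopf("epithelium mask is empty: cortex depth is undefined without a reference surface")
  d <- dim(tissue_mask)
  dist <- array(cpp_edt3d(as.vector(epithelium_mask), d) * voxel_size, d)
  cortex <- tissue_mask & dist <= cortex_depth
  layer_counts <- colSums(matrix(cortex, nrow = d[1] * d[2], ncol = d[3]))
  structure(list(distance_field = dist, cortex_mask = cortex,
                 cortex_depth = cortex_depth, voxel_size = voxel_size,
                 cortical_volume_mm3 = sum(layer_counts) * voxel_size^3 * 1e-9,
                 layer_volume_um3 = layer_counts * voxel_size^3,
                 dims = d), class = "cortex_geometry")
}

#' @export
print.cortex_geometry <- function(x, ...) {
  cat(sprintf("<cortex_geometry> cortex <= %g um, volume %.4f mm^3\n",
              x$cortex_depth, x$cortical_volume_mm3))
  invisible(x)
}

#' Per-oocyte depth below the surface epithelium
#'
#' Depth is the distance field interpolated trilinearly at the oocyte
#' centroid, giving sub-voxel resolution. The alternative convention
#' measures from the oocyte boundary: centroid depth minus the radius,
#' clamped at zero.
#'
#' @param oocytes an oocyte table (see [as_oocyte_table()]).
#' @param geom a [build_cortex()] geometry.
#' @param method `"centroid"` (default) or `"boundary"`.
#' @return `oocytes` with a `depth_um` column (replaced if present).
#' @export
oocyte_depths <- function(oocytes, geom, method = c("centroid", "boundary")) {
  method <- match.arg(method)
  oocytes <- as_oocyte_table(oocytes)
  stopifnot(inherits(geom, "cortex_geometry"))
  if (is.null(geom$distance_field))
    stopf("geometry has no distance field (built without an epithelium)")
  p <- cbind(oocytes$x_um, oocytes$y_um, oocytes$z_um) / geom$voxel_size
  d <- geom$dims
  bad <- which(p[, 1] < 0 | p[, 1] > d[1] - 1 | p[, 2] < 0 |
                 p[, 2] > d[2] - 1 | p[, 3] < 0 | p[, 3] > d[3] - 1)
  if (length(bad))
    stopf("centroid of oocyte id %s lies outside the volume",
          paste(oocytes$id[bad[1]]))
  depth <- interp_trilinear(geom$distance_field, p)
  if (method == "boundary")
    depth <- pmax(0, depth - oocytes$diameter_um / 2)
  oocytes$depth_um <- depth
  oocytes
}

#' Fixed-radius neighbor counts
#'
#' For each oocyte, the number of other oocytes whose centroid lies within
#' `radius` (inclusive) of its own centroid — 40 um by default, the
#' distance reported as the limit of follicular neighbor effects. Computed
#' with uniform grid binning; identical to the quadratic definition.
#'
#' @param oocytes an oocyte table.
#' @param radius neighborhood radius, micrometres.
#' @return `oocytes` with a `neighbor_count` column.
#' @export
neighbor_counts <- function(oocytes, radius = 40) {
  oocytes <- as_oocyte_table(oocytes)
  oocytes$neighbor_count <-
    as.integer(cpp_count_neighbors(cbind(oocytes$x_um, oocytes$y_um,
                                         oocytes$z_um), radius))
  oocytes
}

#' Volumetric oocyte density in the cortex
#'
#' Oocytes whose centroid falls in a cortex voxel, divided by the cortical
#' volume. An oocyte straddling the cortical boundary counts iff its
#' centroid is inside.
#'
#' @param oocytes an oocyte table.
#' @param geom a [build_cortex()] geometry (or any list with `cortex_mask`,
#'   `voxel_size`, `cortical_volume_mm3`).
#' @return Oocytes per mm^3 of cortex.
#' @export
density_3d <- function(oocytes, geom) {
  oocytes <- as_oocyte_table(oocytes)
  if (geom$cortical_volume_mm3 <= 0)
    stopf("cortical volume is zero; density undefined")
  if (nrow(oocytes) == 0) return(0)
  d <- dim(geom$cortex_mask)
  idx <- cbind(round(oocytes$x_um / geom$voxel_size) + 1,
               round(oocytes$y_um / geom$voxel_size) + 1,
               round(oocytes$z_um / geom$voxel_size) + 1)
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
    idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
  n_in <- sum(geom$cortex_mask[idx[inside, , drop = FALSE]])
  n_in / geom$cortical_volume_mm3
}

#' Flag oocytes in dense clusters
#'
#' Subset of oocytes with at least `threshold` neighbors (default 10, the
#' display rule for focal clustering). Row order is preserved.
#'
#' @param oocytes an oocyte table with a `neighbor_count` column.
#' @param threshold minimum neighbor count.
#' @return The filtered table.
#' @export
cluster_flags <- function(oocytes, threshold = 10) {
  oocytes <- as_oocyte_table(oocytes)
  if (!"neighbor_count" %in% names(oocytes))
    stopf("run neighbor_counts() first: no neighbor_count column")
  oocytes[oocytes$neighbor_count >= threshold, , drop = FALSE]
}
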