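# From binary oocyte masks to clean instances: thresholding, connected
# components, watershed separation of touching oocytes, removal of noise
# specks and elongated vessel fragments, and segmentation scoring.

#' Instance post-processing parameters
#'
#' Thresholds for turning a binary oocyte mask into instances. Defaults are
#' conservative for 30-40 um primordial oocytes: the noise floor is the
#' volume of a 10 um sphere, watershed markers must be at least 15 um
#' apart, and components whose principal-axis elongation exceeds 4 are
#' discarded as vessel fragments (tubes being the alternative hypothesis to
#' spheres).
#'
#' @param connectivity voxel connectivity, one of 6, 18, 26.
#' @param min_volume minimum instance volume, cubic micrometres.
#' @param split_min_distance minimum separation between watershed markers,
#'   micrometres.
#' @param vessel_elongation major/minor principal-axis length ratio above
#'   which a component is removed as a vessel; `Inf` disables the filter.
#' @param erode_voxels optional isotropic erosion (in voxels) applied to
#'   the mask before labeling, emulating a deliberate boundary shrinkage
#'   sometimes used to prevent instance merging; default 0 (off).
#' @return A list of class `instance_params`.
#' @export
instance_params <- function(connectivity = 26L,
                            min_volume = pi * 10^3 / 6,
                            split_min_distance = 15,
                            vessel_elongation = 4,
                            erode_voxels = 0L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stopf("connectivity must be 6, 18 or 26")
  if (min_volume < 0) stopf("min_volume must be >= 0")
  if (split_min_distance <= 0) stopf("split_min_distance must be > 0")
  if (vessel_elongation <= 1) stopf("vessel_elongation must be > 1")
  structure(list(connectivity = as.integer(connectivity),
                 min_volume = min_volume,
                 split_min_distance = split_min_distance,
                 vessel_elongation = vessel_elongation,
                 erode_voxels = as.integer(erode_voxels)),
            class = "instance_params")
}

#' Otsu threshold of a numeric vector or array
#'
#' Maximizes the between-class variance over a fixed-bin histogram.
#' Degenerate (constant) input is an error.
#'
#' @param x numeric values.
#' @param nbins histogram bins.
#' @return The threshold value (a bin boundary).
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stopf("degenerate histogram: image is constant, Otsu threshold undefined")
  brk <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(x, brk, rightmost.closed = TRUE),
                           nbins))
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[nbins]; mtot <- m[nbins]
  w1 <- w[-nbins]; m1 <- m[-nbins]
  valid <- w1 > 0 & w1 < n
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (mtot * w1[valid] - n * m1[valid])^2 /
    (w1[valid] * (n - w1[valid]))
  # the objective is flat over empty gaps between modes; take the middle
  # of the argmax plateau (the EBImage convention)
  opt <- which(bcv >= max(bcv) * (1 - 1e-12))
  brk[opt[ceiling(length(opt) / 2)] + 1L]
}

#' Threshold an intensity volume into a binary oocyte mask
#'
#' Oocytes are hypodense (dark), so the mask is the set of below-threshold
#' voxels. When an epithelium mask is supplied, those voxels are excluded
#' both from the Otsu histogram (which would otherwise see three classes)
#' and from the output mask.
#'
#' @param intensity an `intensity_volume` (see [render_intensity()]) or a
#'   3D numeric array.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold value when `method = "fixed"`.
#' @param epithelium_mask optional logical array of epithelium voxels.
#' @return A logical array.
#' @export
threshold_segment <- function(intensity, method = c("otsu", "fixed"),
                              threshold = NULL, epithelium_mask = NULL) {
  method <- match.arg(method)
  grid <- if (inherits(intensity, "intensity_volume")) intensity$grid
          else intensity
  check_dim3(grid, "intensity")
  vals <- if (is.null(epithelium_mask)) grid else grid[!epithelium_mask]
  thr <- switch(method,
                otsu = otsu_threshold(vals),
                fixed = {
                  if (is.null(threshold))
                    stopf("method = 'fixed' needs a threshold")
                  threshold
                })
  mask <- grid < thr
  if (!is.null(epithelium_mask)) mask <- mask & !epithelium_mask
  mask
}

#' Extract oocyte instances from a binary mask
#'
#' The automated equivalent of manual segmentation clean-up: connected
#' components under the chosen connectivity; components whose interior
#' distance transform holds two or more local maxima at least
#' `split_min_distance` apart are split by marker-controlled watershed on
#' the negated distance transform; instances smaller than `min_volume` are
#' dropped as noise; instances with principal-axis elongation above
#' `vessel_elongation` are dropped as vessel fragments. Marker selection is
#' fully deterministic: candidate maxima are ranked by distance value, ties
#' broken by lexicographic voxel index, and greedily thinned to the minimum
#' spacing within each component.
#'
#' @param mask logical 3D array.
#' @param params an [instance_params()].
#' @param voxel_size voxel size, micrometres.
#' @return A list with `volume` (a [labeled_volume()], instances labeled
#'   1..n in order of first voxel) and `oocytes` (table with id, centroid
#'   x/y/z um, equivalent sphere diameter um, volume um^3, n_voxels,
#'   elongation).
#' @export
extract_instances <- function(mask, params = instance_params(), voxel_size) {
  check_dim3(mask, "mask")
  stopifnot(inherits(params, "instance_params"))
  d <- dim(mask)
  empty <- list(volume = labeled_volume(array(0L, d), voxel_size),
                oocytes = data.frame(id = integer(0), x_um = numeric(0),
                                     y_um = numeric(0), z_um = numeric(0),
                                     diameter_um = numeric(0),
                                     volume_um3 = numeric(0),
                                     n_voxels = integer(0),
                                     elongation = numeric(0)))
  if (!any(mask)) return(empty)

  edt <- cpp_edt3d(!mask, dim(mask)) * voxel_size
  if (params$erode_voxels > 0L) {
    mask <- array(edt > params$erode_voxels * voxel_size, d)
    if (!any(mask)) return(empty)
  }
  comp <- cpp_label3d(mask, d, params$connectivity)
  ncomp <- max(comp)

  # deterministic marker selection per component. A connected plateau of
  # equal-valued maxima (e.g. the ridge of a tube) is one candidate, not a
  # chain of them: collapse each connected candidate group to its
  # highest-valued, lowest-index voxel.
  cand_mask <- cpp_local_maxima(edt, as.vector(mask), d)
  cand_lab <- cpp_label3d(cand_mask, d, 26L)
  cand_all <- which(cand_mask)
  grp <- cand_lab[cand_all]
  pick <- cand_all[order(grp, -edt[cand_all], cand_all)]
  cand <- pick[!duplicated(sort(grp))]
  ord <- order(comp[cand], -edt[cand], cand)
  cand <- cand[ord]
  coords <- arrayInd(cand, d) # 1-based voxel indices
  markers_idx <- integer(0)
  if (length(cand)) {
    keep <- logical(length(cand))
    split_d2 <- (params$split_min_distance / voxel_size)^2
    start <- 1L
    ccomp <- comp[cand]
    while (start <= length(cand)) {
      end <- start
      while (end < length(cand) && ccomp[end + 1L] == ccomp[start]) end <- end + 1L
      sel <- integer(0)
      for (i in start:end) {
        if (length(sel) == 0L) { sel <- i; keep[i] <- TRUE; next }
        d2 <- (coords[sel, 1] - coords[i, 1])^2 +
          (coords[sel, 2] - coords[i, 2])^2 +
          (coords[sel, 3] - coords[i, 3])^2
        if (all(d2 >= split_d2)) { sel <- c(sel, i); keep[i] <- TRUE }
      }
      start <- end + 1L
    }
    markers_idx <- cand[keep]
  }

  if (length(markers_idx) > ncomp) {
    markers <- integer(length(comp))
    markers[markers_idx] <- seq_along(markers_idx)
    lab <- cpp_watershed(edt, markers, as.vector(mask), d,
                         params$connectivity)
  } else {
    lab <- comp
  }

  lab <- array(lab, d)
  nlab <- max(lab)
  st <- cpp_label_stats(as.vector(lab), d, nlab)
  nvox <- st[, 1]
  vol_um3 <- nvox * voxel_size^3
  keep <- vol_um3 >= params$min_volume & nvox > 0

  # principal-axis elongation from the voxel covariance (+ the voxel's own
  # second moment, so single-plane components stay finite)
  elong <- rep(NA_real_, nlab)
  for (l in which(keep)) {
    n <- st[l, 1]
    mu <- st[l, 2:4] / n
    cv <- matrix(c(st[l, 5] / n - mu[1]^2, st[l, 8] / n - mu[1] * mu[2],
                   st[l, 9] / n - mu[1] * mu[3],
                   st[l, 8] / n - mu[1] * mu[2], st[l, 6] / n - mu[2]^2,
                   st[l, 10] / n - mu[2] * mu[3],
                   st[l, 9] / n - mu[1] * mu[3],
                   st[l, 10] / n - mu[2] * mu[3],
                   st[l, 7] / n - mu[3]^2), 3, 3)
    ev <- eigen(cv + diag(1 / 12, 3), symmetric = TRUE,
                only.values = TRUE)$values
    elong[l] <- sqrt(max(ev) / min(ev))
  }
  if (is.finite(params$vessel_elongation))
    keep <- keep & !is.na(elong) & elong <= params$vessel_elongation

  survivors <- which(keep)
  if (length(survivors) == 0L) return(empty)
  # relabel 1..n in order of first voxel occurrence
  idx_any <- which(lab > 0L)
  first_order <- lab[idx_any][!duplicated(lab[idx_any])]
  survivors <- first_order[first_order %in% survivors]
  remap <- integer(nlab)
  remap[survivors] <- seq_along(survivors)
  out <- array(0L, d)
  out[idx_any] <- remap[lab[idx_any]]

  tab <- data.frame(id = seq_along(survivors),
                    x_um = st[survivors, 2] / st[survivors, 1] * voxel_size,
                    y_um = st[survivors, 3] / st[survivors, 1] * voxel_size,
                    z_um = st[survivors, 4] / st[survivors, 1] * voxel_size,
                    diameter_um = (6 * st[survivors, 1] * voxel_size^3 /
                                     pi)^(1 / 3),
                    volume_um3 = st[survivors, 1] * voxel_size^3,
                    n_voxels = as.integer(st[survivors, 1]),
                    elongation = elong[survivors])
  list(volume = labeled_volume(out, voxel_size), oocytes = tab)
}

#' Voxelwise segmentation scores
#'
#' Dice, precision and recall between a predicted and a reference binary
#' mask. Two empty masks score 1 across the board by convention.
#'
#' @param predicted,truth logical arrays of identical shape.
#' @return A list of class `seg_scores` with `dice`, `precision`, `recall`.
#' @export
segmentation_scores <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth)))
    stopf("mask shapes differ: %s vs %s",
          paste(dim(predicted), collapse = "x"),
          paste(dim(truth), collapse = "x"))
  np <- sum(predicted)
  nt <- sum(truth)
  if (np == 0 && nt == 0)
    return(structure(list(dice = 1, precision = 1, recall = 1),
                     class = "seg_scores"))
  inter <- sum(predicted & truth)
  precision <- if (np > 0) inter / np else 0
  recall <- if (nt > 0) inter / nt else 0
  structure(list(dice = 2 * inter / (np + nt), precision = precision,
                 recall = recall), class = "seg_scores")
}

#' @export
print.seg_scores <- function(x, ...) {
  cat(sprintf("<seg_scores> dice %.4f, precision %.4f, recall %.4f\n",
              x$dice, x$precision, x$recall))
  invisible(x)
}
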