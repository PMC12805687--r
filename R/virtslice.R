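# Virtual histology: sectioning a known spherical oocyte population into
# slabs, extracting per-section profiles, and estimating density with a
# Schmidt/Abercrombie-type duplicate-count correction
#   N_hat = P * k * t / (t + Dbar)
# where P is the profile count over analyzed sections, t the section
# thickness, k the sampling interval, and Dbar the mean diameter of the
# largest 10% of sectioned oocytes. Sweeps over interval and starting
# offset quantify the bias and variability of sparse 2D sampling.

#' Sectioning design
#'
#' Physical sections are 1-based and tile the z axis in half-open slabs
#' `[(s-1)t, s t)`. The clinical five-section design is sections 10, 20,
#' 30, 40, 50: `sectioning_design(start = 10, interval = 10, n_analyzed =
#' 5)`.
#'
#' @param thickness section thickness t, micrometres (default 4).
#' @param interval sampling interval k: every k-th section is analyzed
#'   (default 10).
#' @param start 1-based index of the first analyzed section.
#' @param n_analyzed number of analyzed sections, or `"all"` for every
#'   feasible section from `start`.
#' @param axis sectioning axis, `"x"`, `"y"` or `"z"`. Histological
#'   sections of a cortical strip are cut across the strip, perpendicular
#'   to the surface epithelium, so for a phantom whose epithelium is the
#'   z = 0 plane the faithful choice is `"x"` (or `"y"`): each section then
#'   contains the full depth gradient. Sectioning parallel to the surface
#'   (`"z"` for that phantom) confounds the depth profile with the
#'   sampling design.
#' @return A list of class `sectioning_design`.
#' @export
sectioning_design <- function(thickness = 4, interval = 10L, start = 1L,
                              n_analyzed = "all", axis = "z") {
  if (thickness <= 0) stopf("thickness must be > 0")
  if (interval < 1) stopf("interval must be >= 1")
  if (start < 1) stopf("start must be >= 1")
  if (!axis %in% c("x", "y", "z")) stopf("axis must be 'x', 'y' or 'z'")
  if (!identical(n_analyzed, "all") &&
      (!is.numeric(n_analyzed) || n_analyzed < 1))
    stopf("n_analyzed must be a positive count or \"all\"")
  structure(list(thickness = thickness, interval = as.integer(interval),
                 start = as.integer(start), n_analyzed = n_analyzed,
                 axis = axis),
            class = "sectioning_design")
}

#' Physical spacing between analyzed sections
#'
#' @param design a [sectioning_design()].
#' @return Spacing in micrometres (`interval * thickness`); 4 um sections
#'   sampled every 10th are 40 um apart.
#' @export
section_spacing <- function(design) {
  stopifnot(inherits(design, "sectioning_design"))
  design$interval * design$thickness
}

axis_dim <- function(axis) match(axis, c("x", "y", "z"))

n_sections_available <- function(geom, thickness, axis = "z") {
  floor(geom$dims[axis_dim(axis)] * geom$voxel_size / thickness)
}

# cortex volume (um^3) per voxel layer along the given axis
cortex_layer_volumes <- function(geom, axis = "z") {
  ad <- axis_dim(axis)
  if (ad == 3L && !is.null(geom$layer_volume_um3))
    return(geom$layer_volume_um3)
  m <- geom$cortex_mask
  d <- dim(m)
  counts <- switch(ad,
                   rowSums(matrix(m, nrow = d[1])),
                   rowSums(matrix(colSums(matrix(m, nrow = d[1])),
                                  nrow = d[2])),
                   colSums(matrix(m, ncol = d[3])))
  counts * geom$voxel_size^3
}

analyzed_sections <- function(design, n_avail) {
  if (design$start > n_avail)
    stopf("design start %d beyond sample extent: only %d sections of %g um available",
          design$start, n_avail, design$thickness)
  s <- seq.int(design$start, n_avail, by = design$interval)
  if (!identical(design$n_analyzed, "all")) {
    if (length(s) < design$n_analyzed)
      stopf("only %d analyzed sections fit the sample extent (%d requested)",
            length(s), design$n_analyzed)
    s <- s[seq_len(design$n_analyzed)]
  }
  s
}

# cortical slab area (mm^2) for each section: cortex volume overlapping the
# slab, divided by the slab thickness
slab_areas_mm2 <- function(geom, sections, thickness, axis = "z") {
  vox <- geom$voxel_size
  lv <- cortex_layer_volumes(geom, axis)
  nz <- length(lv)
  zc <- (seq_len(nz) - 1) * vox # layer centers
  vapply(sections, function(s) {
    a <- (s - 1) * thickness
    b <- s * thickness
    k <- which(zc + vox / 2 > a & zc - vox / 2 < b)
    if (!length(k)) return(0)
    ov <- pmin(b, zc[k] + vox / 2) - pmax(a, zc[k] - vox / 2)
    sum(lv[k] * ov / vox) / thickness * 1e-6
  }, numeric(1))
}

#' Virtually section an oocyte population
#'
#' Treats each oocyte as a sphere (center + diameter) and intersects it
#' with the analyzed slabs. A sphere appears in a section iff its z extent
#' overlaps the slab with positive measure (boundary-grazing spheres are
#' never counted) and its largest in-slab circle diameter is at least
#' `visibility_floor` (small polar caps are undetectable in real
#' histology; set 0 for pure geometry). The profile diameter is the true
#' diameter if the equator lies inside the slab, else the chord at the
#' nearest slab face. Cortical slab areas come from the 3D cortex mask.
#'
#' @param oocytes an oocyte table.
#' @param geom a [build_cortex()] geometry.
#' @param design a [sectioning_design()].
#' @param visibility_floor minimum detectable profile diameter, um.
#' @return An object of class `section_profiles`: `profiles` (section, id,
#'   diameter_um), `sections` (section, z0_um, z1_um, area_mm2), `design`,
#'   `visibility_floor`, `n_avail`.
#' @export
make_profiles <- function(oocytes, geom, design = sectioning_design(),
                          visibility_floor = 5) {
  oocytes <- as_oocyte_table(oocytes)
  stopifnot(inherits(design, "sectioning_design"))
  t <- design$thickness
  n_avail <- n_sections_available(geom, t, design$axis)
  secs <- analyzed_sections(design, n_avail)

  if (nrow(oocytes) > 0) {
    z <- oocytes[[paste0(design$axis, "_um")]]
    R <- oocytes$diameter_um / 2
    s_min <- pmax(1L, floor((z - R) / t) + 1L)
    s_max <- pmin(n_avail, ceiling((z + R) / t + 1) - 1L)
    cnt <- pmax(0L, s_max - s_min + 1L)
    sec <- sequence(cnt, from = s_min, by = 1L)
    id <- rep(oocytes$id, cnt)
    zz <- rep(z, cnt)
    RR <- rep(R, cnt)
    a <- (sec - 1) * t
    b <- sec * t
    delta <- pmax(0, pmax(a - zz, zz - b))
    chord <- ifelse(delta >= RR, 0, 2 * sqrt(pmax(0, RR^2 - delta^2)))
    # strict overlap: exclude zero-measure grazing contacts
    ok <- (zz + RR > a) & (zz - RR < b) & chord > 0 &
      chord >= visibility_floor & sec %in% secs
    prof <- data.frame(section = sec[ok], id = id[ok],
                       diameter_um = chord[ok])
  } else {
    prof <- data.frame(section = integer(0), id = integer(0),
                       diameter_um = numeric(0))
  }
  sections <- data.frame(section = secs, z0_um = (secs - 1) * t,
                         z1_um = secs * t,
                         area_mm2 = slab_areas_mm2(geom, secs, t,
                                                   design$axis))
  structure(list(profiles = prof, sections = sections, design = design,
                 visibility_floor = visibility_floor, n_avail = n_avail),
            class = "section_profiles")
}

# restrict a full (interval 1) profile set to a sparser design
subset_profiles <- function(profiles, secs, design) {
  structure(list(profiles = profiles$profiles[
                   profiles$profiles$section %in% secs, , drop = FALSE],
                 sections = profiles$sections[
                   profiles$sections$section %in% secs, , drop = FALSE],
                 design = design,
                 visibility_floor = profiles$visibility_floor,
                 n_avail = profiles$n_avail),
            class = "section_profiles")
}

#' Corrected histological density estimate
#'
#' Applies the duplicate-count correction to a profile set: with P profiles
#' over the analyzed sections and Dbar the mean of the largest
#' `top_fraction` of per-oocyte maximum profile diameters, the corrected
#' count is `N_hat = P k t / (t + Dbar)` and the examined cortical volume
#' extrapolates each analyzed section over its sampling period,
#' `V_ext = sum(A_i) k t`. The exact identity `density_corrected =
#' density_uncorrected * t / (t + Dbar)` holds by construction.
#'
#' @param profiles a [make_profiles()] result.
#' @param top_fraction fraction of largest oocytes defining Dbar (default
#'   0.1; at least one oocyte is always used).
#' @param dbar_mode `"per_oocyte"` deduplicates profiles to each oocyte's
#'   maximum diameter before taking the top fraction (the "largest 10% of
#'   oocytes"); `"pooled"` ranks raw profiles instead.
#' @return A list of class `histology_estimate`: `P`, `dbar_um`, `n_hat`,
#'   `v_ext_mm3`, `density_corrected`, `density_uncorrected` (both per
#'   mm^3), plus the design parameters.
#' @export
estimate_density <- function(profiles, top_fraction = 0.1,
                             dbar_mode = c("per_oocyte", "pooled")) {
  stopifnot(inherits(profiles, "section_profiles"))
  dbar_mode <- match.arg(dbar_mode)
  t <- profiles$design$thickness
  k <- profiles$design$interval
  A <- sum(profiles$sections$area_mm2)
  if (A <= 0) stopf("zero total cortical area in the analyzed sections")
  P <- nrow(profiles$profiles)
  if (P == 0) {
    est <- list(P = 0L, dbar_um = NA_real_, n_hat = 0,
                v_ext_mm3 = A * k * t * 1e-3,
                density_corrected = 0, density_uncorrected = 0,
                thickness = t, interval = k)
    return(structure(est, class = "histology_estimate"))
  }
  diam <- switch(dbar_mode,
                 per_oocyte = vapply(split(profiles$profiles$diameter_um,
                                           profiles$profiles$id),
                                     max, numeric(1)),
                 pooled = profiles$profiles$diameter_um)
  ntop <- max(1L, ceiling(top_fraction * length(diam)))
  dbar <- mean(sort(diam, decreasing = TRUE)[seq_len(ntop)])
  n_hat <- P * k * t / (t + dbar)
  v_ext <- A * k * t * 1e-3 # mm^2 * um -> mm^3
  structure(list(P = P, dbar_um = dbar, n_hat = n_hat, v_ext_mm3 = v_ext,
                 density_corrected = n_hat / v_ext,
                 density_uncorrected = P / (A * t * 1e-3),
                 thickness = t, interval = k),
            class = "histology_estimate")
}

#' @export
print.histology_estimate <- function(x, ...) {
  cat(sprintf(paste0("<histology_estimate> P = %d profiles, Dbar = %s um\n",
                     "  corrected %.1f /mm^3, uncorrected %.1f /mm^3 ",
                     "(t = %g um, k = %d)\n"),
              x$P, ifelse(is.na(x$dbar_um), "NA", sprintf("%.1f", x$dbar_um)),
              x$density_corrected, x$density_uncorrected, x$thickness,
              x$interval))
  invisible(x)
}

#' Sweep the starting offset of a sparse sectioning series
#'
#' Re-estimates density for every feasible starting section of an
#' `n_analyzed`-section series, quantifying how much a sparse design's
#' answer depends on where the series happens to begin.
#'
#' @param oocytes,geom as in [make_profiles()].
#' @param thickness,interval,n_analyzed design parameters.
#' @param visibility_floor minimum detectable profile diameter, um.
#' @return A list with `estimates` (data.frame: start, P, dbar_um,
#'   density_corrected, density_uncorrected) and `summary` (min, max,
#'   median, cv of the corrected density).
#' @export
offset_sweep <- function(oocytes, geom, thickness = 4, interval = 10L,
                         n_analyzed = 5L, visibility_floor = 5,
                         axis = "z") {
  full <- make_profiles(oocytes, geom,
                        sectioning_design(thickness, 1L, 1L, "all", axis),
                        visibility_floor)
  n_avail <- full$n_avail
  max_start <- n_avail - (n_analyzed - 1L) * interval
  if (max_start < 1)
    stopf("no feasible start: %d sections needed, %d available",
          (n_analyzed - 1L) * interval + 1L, n_avail)
  rows <- lapply(seq_len(max_start), function(st) {
    secs <- seq.int(st, by = interval, length.out = n_analyzed)
    e <- estimate_density(subset_profiles(full, secs,
           sectioning_design(thickness, interval, st, n_analyzed, axis)))
    data.frame(start = st, P = e$P, dbar_um = e$dbar_um,
               density_corrected = e$density_corrected,
               density_uncorrected = e$density_uncorrected)
  })
  est <- do.call(rbind, rows)
  dc <- est$density_corrected
  cv <- if (length(dc) > 1 && mean(dc) > 0) sd(dc) / mean(dc) else 0
  list(estimates = est,
       summary = c(min = min(dc), max = max(dc), median = median(dc),
                   cv = cv))
}

#' Sweep the sectioning interval
#'
#' Corrected density at every interval k in `k_range`, analyzing all
#' feasible sections from `start` at each k. The k = 1 row is the
#' all-sections estimate that sparser designs are judged against.
#'
#' @param oocytes,geom as in [make_profiles()].
#' @param thickness section thickness, um.
#' @param k_range intervals to evaluate (must include 1 for
#'   [stability_horizon()]).
#' @param start first analyzed section.
#' @param visibility_floor minimum detectable profile diameter, um.
#' @return A data.frame (k, P, dbar_um, density_corrected,
#'   density_uncorrected, rel_dev) where `rel_dev` is the relative
#'   deviation from the k = 1 corrected estimate (NA if 1 is not in
#'   `k_range`).
#' @export
interval_sweep <- function(oocytes, geom, thickness = 4, k_range = 1:20,
                           start = 1L, visibility_floor = 5, axis = "z") {
  full <- make_profiles(oocytes, geom,
                        sectioning_design(thickness, 1L, 1L, "all", axis),
                        visibility_floor)
  n_avail <- full$n_avail
  rows <- lapply(k_range, function(k) {
    secs <- seq.int(start, n_avail, by = k)
    e <- estimate_density(subset_profiles(full, secs,
           sectioning_design(thickness, k, start, "all", axis)))
    data.frame(k = k, P = e$P, dbar_um = e$dbar_um,
               density_corrected = e$density_corrected,
               density_uncorrected = e$density_uncorrected)
  })
  out <- do.call(rbind, rows)
  if (1 %in% k_range) {
    ref <- out$density_corrected[out$k == 1][1]
    out$rel_dev <- if (ref > 0) abs(out$density_corrected / ref - 1)
                   else ifelse(out$density_corrected == 0, 0, Inf)
  } else out$rel_dev <- NA_real_
  out
}

#' Largest stable sectioning interval
#'
#' The largest k such that every interval 1..k (those present in the
#' sweep) stays within `tol` of the k = 1 corrected estimate.
#'
#' @param sweep an [interval_sweep()] result.
#' @param tol relative tolerance (default 0.2).
#' @return An integer k.
#' @export
stability_horizon <- function(sweep, tol = 0.2) {
  stopifnot("rel_dev" %in% names(sweep), 1 %in% sweep$k)
  ks <- sort(sweep$k)
  ok <- vapply(ks, function(k) all(sweep$rel_dev[sweep$k <= k] <= tol),
               logical(1))
  if (!any(ok)) return(0L)
  as.integer(max(ks[cumsum(!ok) == 0]))
}

#' Compare 3D counting with the two histological sampling strategies
#'
#' Full-volume 3D density versus (a) every `interval`-th section across the
#' whole sample and (b) the limited five-section clinical series, with
#' relative errors against the 3D value.
#'
#' @param oocytes,geom as in [make_profiles()].
#' @param thickness,interval design parameters.
#' @param five_start first section of the limited series (default 10:
#'   sections 10, 20, 30, 40, 50).
#' @param n_five number of sections in the limited series.
#' @param visibility_floor minimum detectable profile diameter, um.
#' @return A data.frame with one row per strategy (`density_3d`,
#'   `every_kth_full`, `five_sections`): density and relative error vs the
#'   3D value (0 when both are zero).
#' @export
compare_strategies <- function(oocytes, geom, thickness = 4, interval = 10L,
                               five_start = 10L, n_five = 5L,
                               visibility_floor = 5, axis = "z") {
  d3 <- density_3d(oocytes, geom)
  full <- make_profiles(oocytes, geom,
                        sectioning_design(thickness, 1L, 1L, "all", axis),
                        visibility_floor)
  secs_full <- seq.int(five_start, full$n_avail, by = interval)
  e_full <- estimate_density(subset_profiles(full, secs_full,
              sectioning_design(thickness, interval, five_start, "all",
                                axis)))
  secs_five <- seq.int(five_start, by = interval, length.out = n_five)
  if (max(secs_five) > full$n_avail)
    stopf("five-section series needs %d sections, %d available",
          max(secs_five), full$n_avail)
  e_five <- estimate_density(subset_profiles(full, secs_five,
              sectioning_design(thickness, interval, five_start, n_five,
                                axis)))
  relerr <- function(x) if (d3 == 0) ifelse(x == 0, 0, Inf) else x / d3 - 1
  data.frame(strategy = c("density_3d", "every_kth_full", "five_sections"),
             density_per_mm3 = c(d3, e_full$density_corrected,
                                 e_five$density_corrected),
             rel_error = c(0, relerr(e_full$density_corrected),
                           relerr(e_five$density_corrected)))
}
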