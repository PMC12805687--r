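# Synthetic ovarian-cortex phantoms: clustered oocyte positions (Thomas-type
# point process), depth-structured placement below a surface epithelium,
# lognormal diameters, hard-core packing, and sphere rasterization.

#' Phantom specification
#'
#' Describes a synthetic cortical volume: grid geometry, the surface
#' epithelium model, the cluster point process generating oocyte centers,
#' and the depth and diameter laws. Oocyte centers follow a Thomas-type
#' process: Poisson parents (intensity per mm^3 of cortex, i.e. tissue
#' within `cortex_depth` of the epithelium) with depths drawn from
#' `depth_law`, each spawning a Poisson number of offspring scattered
#' isotropically in 3D with Gaussian sd `cluster_sd`. Scattering the whole
#' cluster (rather than re-drawing each offspring depth independently)
#' preserves within-cluster proximity along the depth axis, which is what
#' produces realistic local neighbor counts; the marginal depth
#' distribution remains the depth law smeared by `cluster_sd`.
#'
#' @param dims voxels per axis, length 3 (x, y, z); z is the sectioning and
#'   depth axis for the planar surface model.
#' @param voxel_size isotropic voxel size, micrometres.
#' @param epithelium surface model: `list(model = "plane", thickness = 10)`
#'   places the epithelium at z = 0; `list(model = "cap", thickness, radius)`
#'   uses a spherical cap of the given radius (micrometres) touching z = 0 at
#'   the lateral center, tissue inside the sphere.
#' @param parent_intensity cluster parents per mm^3 of cortex.
#' @param mean_cluster_size expected offspring per parent (>= 1).
#' @param cluster_sd Gaussian scatter sd of offspring around their parent,
#'   micrometres.
#' @param depth_law distribution of parent-center depth below the inner
#'   epithelial surface: `list(dist = "lognormal", median, sigma)`,
#'   `list(dist = "exponential", scale)`, or `list(dist = "uniform", min,
#'   max)` (all micrometres).
#' @param diameter_law `list(median, sigma)`: lognormal oocyte diameters,
#'   micrometres; `sigma = 0` gives a monodisperse population.
#' @param min_gap minimum surface-to-surface separation between oocytes,
#'   micrometres; negative values allow touching/overlap, `-Inf` disables
#'   hard-core thinning entirely.
#' @param cortex_depth cortical depth used as the parent-intensity reference
#'   volume, micrometres.
#' @param seed integer RNG seed; a fixed seed reproduces bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(400L, 400L, 600L), voxel_size = 2.28,
                         epithelium = list(model = "plane", thickness = 10),
                         parent_intensity = 100, mean_cluster_size = 4,
                         cluster_sd = 12,
                         depth_law = list(dist = "lognormal", median = 200,
                                          sigma = 0.6),
                         diameter_law = list(median = 32, sigma = 0.08),
                         min_gap = 1, cortex_depth = 1000, seed = 1L) {
  if (length(dims) != 3L || any(dims <= 0) || any(dims != round(dims)))
    stopf("'dims' must be three positive integers")
  if (voxel_size <= 0) stopf("'voxel_size' must be positive")
  if (parent_intensity < 0) stopf("'parent_intensity' must be >= 0")
  if (mean_cluster_size < 1) stopf("'mean_cluster_size' must be >= 1")
  if (cluster_sd < 0) stopf("'cluster_sd' must be >= 0")
  if (!epithelium$model %in% c("plane", "cap"))
    stopf("epithelium model must be 'plane' or 'cap'")
  if (epithelium$model == "cap" && is.null(epithelium$radius))
    stopf("cap epithelium needs a 'radius'")
  if (!depth_law$dist %in% c("lognormal", "exponential", "uniform"))
    stopf("depth_law$dist must be 'lognormal', 'exponential' or 'uniform'")
  if (is.null(diameter_law$median) || diameter_law$median <= 0)
    stopf("diameter_law$median must be positive")
  structure(list(dims = as.integer(dims), voxel_size = voxel_size,
                 epithelium = epithelium,
                 parent_intensity = parent_intensity,
                 mean_cluster_size = mean_cluster_size,
                 cluster_sd = cluster_sd, depth_law = depth_law,
                 diameter_law = diameter_law, min_gap = min_gap,
                 cortex_depth = cortex_depth, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %d x %d x %d voxels @ %g um, %s surface\n",
                     "  parents %g/mm^3 x cluster %g (sd %g um), depth %s,",
                     " diameter lognormal(%g, %g), min_gap %g, seed %d\n"),
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size,
              x$epithelium$model, x$parent_intensity, x$mean_cluster_size,
              x$cluster_sd, x$depth_law$dist, x$diameter_law$median,
              x$diameter_law$sigma, x$min_gap, x$seed))
  invisible(x)
}

# depth below the inner epithelial surface for an n x 3 coordinate matrix
surface_depth <- function(p, spec) {
  ep <- spec$epithelium
  if (ep$model == "plane") {
    p[, 3] - ep$thickness
  } else {
    L <- (spec$dims - 1L) * spec$voxel_size
    ctr <- c(L[1] / 2, L[2] / 2, ep$radius)
    ep$radius - sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2 +
                       (p[, 3] - ctr[3])^2) - ep$thickness
  }
}

sample_depth <- function(law, n) {
  switch(law$dist,
         lognormal = rlnorm(n, meanlog = log(law$median), sdlog = law$sigma),
         exponential = rexp(n, rate = 1 / law$scale),
         uniform = runif(n, law$min, law$max))
}

sample_diameter <- function(law, n) {
  if (law$sigma == 0) rep(law$median, n)
  else rlnorm(n, meanlog = log(law$median), sdlog = law$sigma)
}

# tissue volume within cortex_depth of the epithelium, mm^3 (parent
# intensity reference). Closed form for the planar surface; seeded Monte
# Carlo for the cap.
reference_volume_mm3 <- function(spec) {
  L <- (spec$dims - 1L) * spec$voxel_size
  tep <- spec$epithelium$thickness
  if (spec$epithelium$model == "plane") {
    depth_extent <- min(spec$cortex_depth, L[3] - tep)
    L[1] * L[2] * max(0, depth_extent) * 1e-9
  } else {
    m <- 20000L
    p <- cbind(runif(m, 0, L[1]), runif(m, 0, L[2]), runif(m, 0, L[3]))
    s <- surface_depth(p, spec)
    mean(s >= 0 & s <= spec$cortex_depth) * prod(L) * 1e-9
  }
}

# draw one parent center at depth `d` below the inner surface
place_at_depth <- function(d, spec) {
  L <- (spec$dims - 1L) * spec$voxel_size
  ep <- spec$epithelium
  if (ep$model == "plane") {
    c(runif(1, 0, L[1]), runif(1, 0, L[2]), ep$thickness + d)
  } else {
    ctr <- c(L[1] / 2, L[2] / 2, ep$radius)
    rho <- ep$radius - ep$thickness - d
    if (rho <= 0) return(NULL)
    # uniform on the sphere zone whose z lies inside the volume
    uz_lo <- max(-1, (0 - ctr[3]) / rho)
    uz_hi <- min(1, (L[3] - ctr[3]) / rho)
    if (uz_lo >= uz_hi) return(NULL)
    uz <- runif(1, uz_lo, uz_hi)
    phi <- runif(1, 0, 2 * pi)
    rxy <- sqrt(max(0, 1 - uz^2))
    p <- ctr + rho * c(rxy * cos(phi), rxy * sin(phi), uz)
    if (p[1] < 0 || p[1] > L[1] || p[2] < 0 || p[2] > L[2]) return(NULL)
    p
  }
}

# sphere of radius r centered at p fully inside the tissue (and grid)?
sphere_in_tissue <- function(p, r, s_depth, spec) {
  L <- (spec$dims - 1L) * spec$voxel_size
  all(p - r >= 0) && all(p + r <= L) && s_depth >= r
}

#' Generate a synthetic cortical volume with known ground truth
#'
#' Draws oocyte centers from the cluster process described in
#' [phantom_spec()], enforces full containment in the tissue and (unless
#' `min_gap = -Inf`) a hard-core separation by rejection sampling, and
#' rasterizes each oocyte as a sphere (a voxel belongs to an oocyte iff the
#' voxel center lies inside the sphere). The rejection loop is bounded at
#' 500 proposals per target oocyte; an infeasibly dense specification fails
#' with a "packing infeasible" error rather than silently under-filling.
#'
#' @param spec a [phantom_spec()].
#' @param rasterize if `FALSE`, skip building the label volume (the masks
#'   and the ground-truth table are still produced); useful for large
#'   point-process simulations where only centers matter.
#' @return An object of class `ground_truth`: list with `label_volume`
#'   (a [labeled_volume()], or `NULL` when `rasterize = FALSE`),
#'   `epithelium_mask`, `tissue_mask` (logical arrays), `oocytes` (table
#'   with columns id, x_um, y_um, z_um, diameter_um, volume_um3, depth_um,
#'   parent_id), `reference_volume_mm3` and `spec`.
#' @export
generate_phantom <- function(spec, rasterize = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec, rasterize))
}

generate_phantom_impl <- function(spec, rasterize) {
  L <- (spec$dims - 1L) * spec$voxel_size
  tep <- spec$epithelium$thickness
  vref <- reference_volume_mm3(spec)
  dmed <- spec$diameter_law$median
  if (min(L) < dmed)
    stopf("volume too small to hold one median-diameter oocyte (%g um)", dmed)

  n_parents <- rpois(1, spec$parent_intensity * vref)
  n_off <- if (n_parents > 0) rpois(n_parents, spec$mean_cluster_size) else integer(0)
  target <- sum(n_off)
  budget <- 500L * max(1L, target)
  used <- 0L

  # accepted oocytes
  cap0 <- max(16L, target)
  P <- matrix(NA_real_, cap0, 3)
  Dm <- numeric(cap0)
  Dep <- numeric(cap0)
  Par <- integer(cap0)
  n_acc <- 0L

  hardcore <- is.finite(spec$min_gap)
  for (ip in seq_len(n_parents)) {
    # parent depth from the depth law, truncated to the feasible range
    parent <- NULL
    for (try in seq_len(1000L)) {
      d <- sample_depth(spec$depth_law, 1)
      if (d < 0 || tep + d > max(L)) next
      parent <- place_at_depth(d, spec)
      if (!is.null(parent)) break
    }
    if (is.null(parent)) next
    for (io in seq_len(n_off[ip])) {
      D <- sample_diameter(spec$diameter_law, 1)
      r <- D / 2
      local_try <- 0L
      repeat {
        used <- used + 1L
        if (used > budget)
          stopf(paste0("packing infeasible: hard-core rejection budget ",
                       "exhausted after %d proposals (target %d oocytes, ",
                       "%d placed); reduce density or min_gap"),
                budget, target, n_acc)
        local_try <- local_try + 1L
        # soft-shell cluster: a crowded nest pushes late arrivals outward,
        # so repeated rejections widen the scatter instead of jamming
        p <- parent + rnorm(3) * spec$cluster_sd * (1 + local_try / 150)
        sd_ <- surface_depth(matrix(p, 1), spec)
        if (!sphere_in_tissue(p, r, sd_, spec)) next
        if (hardcore && n_acc > 0L) {
          i <- seq_len(n_acc)
          d2 <- (P[i, 1] - p[1])^2 + (P[i, 2] - p[2])^2 + (P[i, 3] - p[3])^2
          lim <- (Dm[i] + D) / 2 + spec$min_gap
          if (any(d2 < lim^2)) next
        }
        n_acc <- n_acc + 1L
        if (n_acc > nrow(P)) { # grow storage
          P <- rbind(P, matrix(NA_real_, nrow(P), 3))
          Dm <- c(Dm, numeric(length(Dm)))
          Dep <- c(Dep, numeric(length(Dep)))
          Par <- c(Par, integer(length(Par)))
        }
        P[n_acc, ] <- p
        Dm[n_acc] <- D
        Dep[n_acc] <- sd_
        Par[n_acc] <- ip
        break
      }
    }
  }

  i <- seq_len(n_acc)
  oocytes <- data.frame(id = i,
                        x_um = P[i, 1], y_um = P[i, 2], z_um = P[i, 3],
                        diameter_um = Dm[i],
                        volume_um3 = pi * Dm[i]^3 / 6,
                        depth_um = Dep[i], parent_id = Par[i])
  if (n_acc == 0L)
    oocytes <- oocytes[0, , drop = FALSE]

  masks <- phantom_masks(spec)
  lv <- NULL
  if (rasterize) {
    lab <- rasterize_spheres(oocytes, spec$dims, spec$voxel_size)
    lv <- labeled_volume(lab, spec$voxel_size)
  }
  structure(list(label_volume = lv, epithelium_mask = masks$epithelium,
                 tissue_mask = masks$tissue, oocytes = oocytes,
                 reference_volume_mm3 = vref, spec = spec),
            class = "ground_truth")
}

# epithelium / tissue masks on the voxel grid
phantom_masks <- function(spec) {
  d <- spec$dims
  vox <- spec$voxel_size
  tep <- spec$epithelium$thickness
  if (spec$epithelium$model == "plane") {
    zc <- (seq_len(d[3]) - 1) * vox
    epi_z <- zc < tep
    epi <- array(rep(epi_z, each = d[1] * d[2]), dim = d)
    tis <- !epi
  } else {
    L <- (d - 1L) * vox
    ctr <- c(L[1] / 2, L[2] / 2, spec$epithelium$radius)
    dx2 <- ((seq_len(d[1]) - 1) * vox - ctr[1])^2
    dy2 <- ((seq_len(d[2]) - 1) * vox - ctr[2])^2
    dz2 <- ((seq_len(d[3]) - 1) * vox - ctr[3])^2
    s <- spec$epithelium$radius -
      sqrt(outer(outer(dx2, dy2, "+"), dz2, "+")) - tep
    epi <- s >= -tep & s < 0
    tis <- s >= 0
    dim(epi) <- d
    dim(tis) <- d
  }
  list(epithelium = epi, tissue = tis)
}

# voxel-center-in-sphere rasterization; first-come claims contested voxels
rasterize_spheres <- function(oocytes, dims, vox) {
  lab <- array(0L, dim = dims)
  for (i in seq_len(nrow(oocytes))) {
    ctr <- c(oocytes$x_um[i], oocytes$y_um[i], oocytes$z_um[i])
    r <- oocytes$diameter_um[i] / 2
    lo <- pmax(1L, ceiling((ctr - r) / vox) + 1L)
    hi <- pmin(dims, floor((ctr + r) / vox) + 1L)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- ((ix - 1) * vox - ctr[1])^2
    dy2 <- ((iy - 1) * vox - ctr[2])^2
    dz2 <- ((iz - 1) * vox - ctr[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    sub <- lab[ix, iy, iz, drop = FALSE]
    take <- inside & sub == 0L
    sub[take] <- oocytes$id[i]
    lab[ix, iy, iz] <- sub
  }
  lab
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d oocytes, reference cortex %.3f mm^3%s\n",
              nrow(x$oocytes), x$reference_volume_mm3,
              if (is.null(x$label_volume)) " (not rasterized)" else ""))
  invisible(x)
}

#' Calibrated phantom presets for the two age regimes
#'
#' Returns a fixed [phantom_spec()] emulating either a pediatric-like
#' cortex (high density, shallow oocytes, strong clustering; population
#' median depth ~139 um, median neighbor count ~6 within 40 um) or an
#' adult-like cortex (sparse, deep, weak clustering; median depth ~370 um,
#' median neighbors ~2). Parameters were fixed once by large-n simulation;
#' densities differ by more than 3x between regimes.
#'
#' @param regime `"pediatric"` or `"adult"`.
#' @param dims optional grid-size override (problem-size scaling only; the
#'   point-process parameters, and hence densities and medians, are
#'   unchanged).
#' @param seed RNG seed stored in the spec.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(regime = c("pediatric", "adult"), dims = NULL,
                           seed = 1L) {
  regime <- match.arg(regime)
  base <- list(dims = c(400L, 400L, 600L), voxel_size = 2.28,
               epithelium = list(model = "plane", thickness = 10),
               min_gap = 1, cortex_depth = 1000, seed = seed)
  pars <- if (regime == "pediatric") {
    list(parent_intensity = 360, mean_cluster_size = 9, cluster_sd = 13,
         depth_law = list(dist = "lognormal", median = 134, sigma = 0.6),
         diameter_law = list(median = 31, sigma = 0.07),
         min_gap = -10)
  } else {
    list(parent_intensity = 97, mean_cluster_size = 4, cluster_sd = 11.5,
         depth_law = list(dist = "lognormal", median = 370.2, sigma = 0.6),
         diameter_law = list(median = 34, sigma = 0.09),
         min_gap = -4)
  }
  base$min_gap <- NULL
  if (!is.null(dims)) base$dims <- as.integer(dims)
  do.call(phantom_spec, c(base, pars))
}

#' Render a phantom as an intensity volume
#'
#' Emulates the contrast of iodine-stained micro-CT: hypodense (dark)
#' oocytes, mid-grey stroma, hyperdense (bright) epithelium, plus additive
#' Gaussian noise.
#'
#' @param truth a `ground_truth` with a rasterized label volume.
#' @param levels named grey levels `c(oocyte, background, epithelium)`;
#'   must be ordered oocyte < background < epithelium.
#' @param noise_sd additive Gaussian noise sd (same grey units).
#' @param seed RNG seed for the noise.
#' @return A list of class `intensity_volume` with `grid` (double array)
#'   and `voxel_size`.
#' @export
render_intensity <- function(truth,
                             levels = c(oocyte = 40, background = 120,
                                        epithelium = 220),
                             noise_sd = 0, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(truth$label_volume))
    stopf("phantom was generated with rasterize = FALSE; no label volume to render")
  if (!(levels[["oocyte"]] < levels[["background"]] &&
        levels[["background"]] < levels[["epithelium"]]))
    stopf("grey levels must be ordered oocyte < background < epithelium")
  grid <- array(levels[["background"]], dim = dim(truth$label_volume$grid))
  grid[truth$epithelium_mask] <- levels[["epithelium"]]
  grid[truth$label_volume$grid > 0L] <- levels[["oocyte"]]
  if (noise_sd > 0)
    grid <- with_seed(seed, grid + array(rnorm(length(grid), 0, noise_sd),
                                         dim = dim(grid)))
  structure(list(grid = grid, voxel_size = truth$label_volume$voxel_size),
            class = "intensity_volume")
}
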