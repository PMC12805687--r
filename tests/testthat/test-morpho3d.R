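test_that("planar epithelium gives exact layer distances and cortex volumes", {
  d <- c(12L, 12L, 40L)
  epi <- array(FALSE, d); epi[, , 1] <- TRUE # plane at z = 0
  geom <- build_cortex(epi, !epi, 2, cortex_depth = 30)
  for (k in c(2L, 5L, 17L))
    expect_equal(unique(as.vector(geom$distance_field[, , k])), 2 * (k - 1))
  expect_true(all(geom$distance_field[, , 1] == 0))
  # layers 2..16 have distance 2..30 <= 30
  expect_equal(sum(geom$cortex_mask), 12 * 12 * 15)
  gInf <- build_cortex(epi, !epi, 2, cortex_depth = Inf)
  expect_identical(gInf$cortex_mask, !epi)
  expect_error(build_cortex(array(FALSE, d), !epi, 2), "empty")
})

test_that("the distance field matches the all-pairs oracle on random grids", {
  for (seed in 1:3) {
    set.seed(seed)
    d <- c(12L, 10L, 9L)
    epi <- array(runif(prod(d)) < 0.03, d)
    if (!any(epi)) epi[5, 5, 5] <- TRUE
    geom <- build_cortex(epi, !epi, 1.7, cortex_depth = Inf)
    expect_equal(as.vector(geom$distance_field),
                 as.vector(brute_edt(epi, 1.7)), tolerance = 1e-9)
  }
})

test_that("oocyte depths are exact for planar geometry and near-exact generally", {
  d <- c(30L, 30L, 80L)
  epi <- array(FALSE, d); epi[, , 1] <- TRUE
  geom <- build_cortex(epi, !epi, 2.28, cortex_depth = Inf)
  tab <- data.frame(id = 1:2,
                    x_um = c(10, 20) * 2.28, y_um = c(10, 15) * 2.28,
                    z_um = c(0, 139.4), diameter_um = c(30, 30))
  out <- oocyte_depths(tab, geom)
  expect_equal(out$depth_um[1], 0)          # centered on an epithelium voxel
  expect_equal(out$depth_um[2], 139.4)      # sub-voxel planar depth
  outb <- oocyte_depths(tab, geom, method = "boundary")
  expect_equal(outb$depth_um[2], 139.4 - 15)
  expect_equal(outb$depth_um[1], 0)

  # random epithelium: interpolated depth within one voxel diagonal of the
  # brute-force nearest-epithelium-voxel distance
  set.seed(4)
  d2 <- c(15L, 15L, 15L)
  epi2 <- array(runif(prod(d2)) < 0.05, d2)
  epi2[3, 3, 1] <- TRUE
  geom2 <- build_cortex(epi2, !epi2, 2, cortex_depth = Inf)
  n <- 100
  p <- cbind(runif(n, 0, 14), runif(n, 0, 14), runif(n, 0, 14)) * 2
  tab2 <- data.frame(id = 1:n, x_um = p[, 1], y_um = p[, 2], z_um = p[, 3],
                     diameter_um = 10)
  got <- oocyte_depths(tab2, geom2)$depth_um
  ec <- (arrayInd(which(epi2), d2) - 1) * 2
  brute <- vapply(seq_len(n), function(i)
    sqrt(min((ec[, 1] - p[i, 1])^2 + (ec[, 2] - p[i, 2])^2 +
               (ec[, 3] - p[i, 3])^2)), numeric(1))
  expect_true(all(abs(got - brute) <= 2 * sqrt(3) + 1e-9))

  tab_bad <- data.frame(id = 99L, x_um = 1e5, y_um = 0, z_um = 0,
                        diameter_um = 30)
  expect_error(oocyte_depths(tab_bad, geom), "99")
})

test_that("neighbor counts equal the quadratic definition", {
  one <- data.frame(id = 1L, x_um = 5, y_um = 5, z_um = 5,
                    diameter_um = 30)
  expect_identical(neighbor_counts(one)$neighbor_count, 0L)
  pair <- function(gap) data.frame(id = 1:2, x_um = c(0, gap),
                                   y_um = 0, z_um = 0, diameter_um = 30)
  expect_identical(neighbor_counts(pair(40.0))$neighbor_count, c(1L, 1L))
  expect_identical(neighbor_counts(pair(40.001))$neighbor_count, c(0L, 0L))

  set.seed(8)
  n <- 500
  tab <- data.frame(id = 1:n, x_um = runif(n, 0, 400),
                    y_um = runif(n, 0, 400), z_um = runif(n, 0, 400),
                    diameter_um = 30)
  got <- neighbor_counts(tab, radius = 40)$neighbor_count
  expect_identical(got, brute_neighbors(cbind(tab$x_um, tab$y_um,
                                              tab$z_um), 40))
  # radius monotonicity
  got60 <- neighbor_counts(tab, radius = 60)$neighbor_count
  expect_true(all(got60 >= got))
})

test_that("neighbor relations are symmetric", {
  set.seed(3)
  n <- 120
  tab <- data.frame(id = 1:n, x_um = runif(n, 0, 150),
                    y_um = runif(n, 0, 150), z_um = runif(n, 0, 150),
                    diameter_um = 30)
  p <- cbind(tab$x_um, tab$y_um, tab$z_um)
  adj <- as.matrix(dist(p)) <= 40
  diag(adj) <- FALSE
  expect_identical(adj, t(adj))
  expect_identical(neighbor_counts(tab, 40)$neighbor_count,
                   as.integer(rowSums(adj)))
})

test_that("cortical density is count over cortical volume", {
  d <- c(20L, 20L, 30L)
  epi <- array(FALSE, d); epi[, , 1] <- TRUE
  geom <- build_cortex(epi, !epi, 10, cortex_depth = 100)
  # cortex: layers 2..11 -> volume 20*20*10 voxels * 1000 um^3
  expect_equal(geom$cortical_volume_mm3, 20 * 20 * 10 * 1000 * 1e-9)
  tab <- data.frame(id = 1:10, x_um = runif(10, 20, 170),
                    y_um = runif(10, 20, 170), z_um = runif(10, 15, 95),
                    diameter_um = 30)
  expect_equal(density_3d(tab, geom), 10 / geom$cortical_volume_mm3)
  deep <- tab; deep$z_um <- deep$z_um + 150 # all below the cortex
  expect_equal(density_3d(deep, geom), 0)
})

test_that("density on clean phantom labels equals truth exactly", {
  sp <- phantom_spec(dims = c(150L, 150L, 250L), parent_intensity = 700,
                     mean_cluster_size = 2, cluster_sd = 18,
                     depth_law = list(dist = "uniform", min = 25, max = 450),
                     diameter_law = list(median = 30, sigma = 0.05),
                     min_gap = 4, seed = 6)
  tr <- generate_phantom(sp)
  geom <- build_cortex(tr$epithelium_mask, tr$tissue_mask, sp$voxel_size)
  inst <- extract_instances(tr$label_volume$grid > 0L, instance_params(),
                            sp$voxel_size)
  expect_identical(nrow(inst$oocytes), nrow(tr$oocytes))
  expect_equal(density_3d(inst$oocytes, geom),
               nrow(tr$oocytes) / geom$cortical_volume_mm3)
})

test_that("cortical volume grows with cortex depth", {
  d <- c(15L, 15L, 40L)
  epi <- array(FALSE, d); epi[, , 1] <- TRUE
  vols <- vapply(c(20, 40, 60, 1e9), function(cd)
    build_cortex(epi, !epi, 2, cortex_depth = cd)$cortical_volume_mm3,
    numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("cluster flags filter by neighbor count and preserve order", {
  tab <- data.frame(id = 1:4, x_um = 1:4, y_um = 1, z_um = 1,
                    diameter_um = 30, neighbor_count = c(12L, 3L, 10L, 9L))
  got <- cluster_flags(tab)
  expect_identical(got$id, c(1L, 3L))
  expect_identical(cluster_flags(tab, threshold = 0), tab)
  expect_identical(nrow(cluster_flags(tab, threshold = 99)), 0L)
  expect_error(cluster_flags(tab[, -6]), "neighbor_count")
})

test_that("the pediatric regime is more clustered than the adult one", {
  frac_flagged <- function(regime, s) {
    tr <- generate_phantom(phantom_preset(regime,
                                          dims = c(250L, 250L, 500L),
                                          seed = s), rasterize = FALSE)
    oo <- neighbor_counts(tr$oocytes)
    nrow(cluster_flags(oo)) / nrow(oo)
  }
  ped <- vapply(1:5, function(s) frac_flagged("pediatric", s), numeric(1))
  adu <- vapply(1:5, function(s) frac_flagged("adult", s), numeric(1))
  expect_gt(median(ped), median(adu))
})
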