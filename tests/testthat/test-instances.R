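vox <- 2.28

test_that("Otsu threshold agrees with the EBImage reference", {
  set.seed(1)
  x <- c(rnorm(4000, 40, 5), rnorm(16000, 120, 8))
  ours <- otsu_threshold(x, nbins = 256L)
  ref <- EBImage::otsu(EBImage::Image(matrix(x, 100)), range = range(x),
                       levels = 256L)
  binw <- diff(range(x)) / 256
  expect_lt(abs(ours - ref), 2 * binw)
  expect_error(otsu_threshold(rep(3, 100)), "degenerate")
})

test_that("thresholding a noise-free phantom recovers the oocytes exactly", {
  sp <- phantom_spec(dims = c(100L, 100L, 120L), parent_intensity = 800,
                     mean_cluster_size = 2, cluster_sd = 15,
                     depth_law = list(dist = "uniform", min = 25, max = 180),
                     diameter_law = list(median = 32, sigma = 0.05),
                     min_gap = 3, seed = 2)
  tr <- generate_phantom(sp)
  truth_mask <- tr$label_volume$grid > 0L
  img <- render_intensity(tr, noise_sd = 0)
  mask <- threshold_segment(img, epithelium_mask = tr$epithelium_mask)
  expect_identical(as.vector(mask), as.vector(truth_mask))
  expect_false(any(threshold_segment(
    array(120, c(5, 5, 5)), method = "fixed", threshold = 80)))

  imgn <- render_intensity(tr, noise_sd = 4, seed = 5) # 5% of contrast
  maskn <- threshold_segment(imgn, epithelium_mask = tr$epithelium_mask)
  sc <- segmentation_scores(maskn, truth_mask)
  expect_gte(sc$dice, 0.9)
})

test_that("two disjoint spheres give two instances at their true centers", {
  ctr <- rbind(c(50, 60, 60), c(150, 60, 60))
  m <- sphere_mask(c(90L, 50L, 50L), ctr, c(36, 36), vox)
  res <- extract_instances(m, instance_params(), vox)
  expect_identical(nrow(res$oocytes), 2L)
  got <- as.matrix(res$oocytes[order(res$oocytes$x_um),
                               c("x_um", "y_um", "z_um")])
  expect_true(all(abs(got - ctr) < vox))
  # equivalent diameter within the rasterization error bound
  expect_true(all(abs(res$oocytes$diameter_um / 36 - 1) < 0.05))
})

test_that("touching spheres are split by the watershed", {
  ctr <- rbind(c(60, 55, 55), c(90, 55, 55)) # 30 um apart, D = 36: merged
  m <- sphere_mask(c(70L, 50L, 50L), ctr, c(36, 36), vox)
  comp <- flood_fill_labels(m)
  expect_identical(max(comp), 1L) # genuinely merged before splitting
  res <- extract_instances(m, instance_params(), vox)
  expect_identical(nrow(res$oocytes), 2L)
  got <- res$oocytes[order(res$oocytes$x_um), ]
  expect_lt(abs(got$x_um[1] - 60), 6)
  expect_lt(abs(got$x_um[2] - 90), 6)
})

test_that("elongated vessel fragments are removed, spheres kept", {
  # a 200 x 10 x 10 um box: principal-axis ratio ~20
  m <- array(FALSE, c(100L, 40L, 40L))
  m[5:92, 18:22, 18:22] <- TRUE
  res <- extract_instances(m, instance_params(vessel_elongation = 5), vox)
  expect_identical(nrow(res$oocytes), 0L)
  res2 <- extract_instances(m, instance_params(vessel_elongation = Inf),
                            vox)
  expect_identical(nrow(res2$oocytes), 1L)
})

test_that("tiny specks fall below the noise floor", {
  m <- array(FALSE, c(30L, 30L, 30L))
  m[5:7, 5:7, 5:7] <- TRUE          # 27 voxels ~ 320 um^3 < 524
  m[15:24, 15:24, 15:24] <- TRUE    # 1000 voxels, kept
  res <- extract_instances(m, instance_params(), vox)
  expect_identical(nrow(res$oocytes), 1L)
  expect_gt(res$oocytes$volume_um3, 5000)
})

test_that("with filters off, instance extraction is pure connected components", {
  for (seed in 1:4) {
    set.seed(seed)
    d <- c(14L, 12L, 10L)
    m <- array(runif(prod(d)) < 0.25, d)
    for (conn in c(6L, 26L)) {
      oracle <- flood_fill_labels(m, conn)
      res <- extract_instances(
        m, instance_params(connectivity = conn, min_volume = 0,
                           split_min_distance = 1e6,
                           vessel_elongation = Inf), 1)
      expect_identical(as.vector(res$volume$grid), as.vector(oracle))
    }
  }
})

test_that("instance counts are connectivity-invariant for separated spheres", {
  sp <- phantom_spec(dims = c(110L, 110L, 130L), parent_intensity = 500,
                     mean_cluster_size = 2, cluster_sd = 20,
                     depth_law = list(dist = "uniform", min = 25, max = 200),
                     diameter_law = list(median = 30, sigma = 0.05),
                     min_gap = 4, seed = 9) # gap > 1 voxel
  tr <- generate_phantom(sp)
  m <- tr$label_volume$grid > 0L
  n6 <- nrow(extract_instances(m, instance_params(connectivity = 6L),
                               vox)$oocytes)
  n26 <- nrow(extract_instances(m, instance_params(connectivity = 26L),
                                vox)$oocytes)
  expect_identical(n6, n26)
  expect_identical(n26, nrow(tr$oocytes)) # clean-mask count recovery
})

test_that("segmentation scores satisfy their exact identities", {
  t1 <- array(FALSE, c(10L, 10L, 5L)); t1[2:7, 2:7, 2:4] <- TRUE
  expect_equal(unclass(segmentation_scores(t1, t1))[1:3],
               list(dice = 1, precision = 1, recall = 1))
  p0 <- array(FALSE, dim(t1)); p0[9, 9, 5] <- TRUE
  sc0 <- segmentation_scores(p0, t1)
  expect_equal(c(sc0$dice, sc0$precision, sc0$recall), c(0, 0, 0))
  # |T| = 200, P a 100-voxel subset
  tT <- array(FALSE, c(20L, 10L, 2L)); tT[1:10, , ] <- TRUE
  pP <- array(FALSE, dim(tT)); pP[1:5, , ] <- TRUE
  sc <- segmentation_scores(pP, tT)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 0.5)
  expect_equal(sc$dice, 200 / 300, tolerance = 1e-12)
  # harmonic identity on random masks
  for (seed in 1:5) {
    set.seed(seed)
    a <- array(runif(1000) < 0.3, c(10L, 10L, 10L))
    b <- array(runif(1000) < 0.3, c(10L, 10L, 10L))
    sc <- segmentation_scores(a, b)
    if (sc$precision + sc$recall > 0)
      expect_equal(sc$dice, 2 * sc$precision * sc$recall /
                     (sc$precision + sc$recall), tolerance = 1e-12)
    expect_true(sc$dice >= 0 && sc$dice <= 1)
  }
  expect_error(segmentation_scores(t1, tT), "shapes differ")
  expect_equal(segmentation_scores(array(FALSE, c(2L, 2L, 2L)),
                                   array(FALSE, c(2L, 2L, 2L)))$dice, 1)
})
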