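mono_table <- function(n, D, zmax, seed, axis_col = "z_um") {
  set.seed(seed)
  tab <- data.frame(id = seq_len(n),
                    x_um = runif(n, 20, 300), y_um = runif(n, 20, 300),
                    z_um = runif(n, D / 2, zmax - D / 2),
                    diameter_um = D)
  tab
}

test_that("the clinical design samples sections 40 um apart", {
  des <- sectioning_design(thickness = 4, interval = 10L, start = 10L,
                           n_analyzed = 5L)
  expect_equal(section_spacing(des), 40)
})

test_that("single-slab spheres and equatorial profiles have exact diameters", {
  geom <- plane_geom(c(20L, 20L, 60L))
  # D = 3 um sphere inside slab 4 (z in [12, 16))
  tab <- data.frame(id = 1L, x_um = 20, y_um = 20, z_um = 14,
                    diameter_um = 3)
  pr <- make_profiles(tab, geom, sectioning_design(4, 1L, 1L, "all"),
                      visibility_floor = 0)
  expect_identical(nrow(pr$profiles), 1L)
  expect_equal(pr$profiles$diameter_um, 3)
  expect_identical(pr$profiles$section, 4L)
  # equator inside a slab: full diameter reported there
  tab2 <- data.frame(id = 1L, x_um = 20, y_um = 20, z_um = 30,
                     diameter_um = 20)
  pr2 <- make_profiles(tab2, geom, sectioning_design(4, 1L, 1L, "all"),
                       visibility_floor = 0)
  expect_equal(max(pr2$profiles$diameter_um), 20)
  # off-equator slabs carry the chord at the nearest face
  away <- pr2$profiles[pr2$profiles$section == 10, ] # slab [36, 40)
  expect_equal(away$diameter_um, 2 * sqrt(10^2 - 6^2))
})

test_that("mean profile multiplicity matches the (D + t)/t closed form", {
  geom <- plane_geom(c(10L, 10L, 500L))
  tab <- mono_table(2000, 36, 1100, seed = 5)
  pr <- make_profiles(tab, geom, sectioning_design(4, 1L, 1L, "all"),
                      visibility_floor = 0)
  mult <- nrow(pr$profiles) / nrow(tab)
  expect_lt(abs(mult / 10 - 1), 0.02) # (36 + 4)/4 = 10
  # no oocyte contributes twice to one section
  expect_false(any(duplicated(pr$profiles[c("section", "id")])))
  # profile diameters never exceed the true diameter
  expect_true(all(pr$profiles$diameter_um <= 36 + 1e-9))
})

test_that("the corrected estimator satisfies its algebraic identities", {
  geom <- plane_geom(c(40L, 40L, 300L))
  for (seed in 1:5) {
    tab <- mono_table(150, 34, 600, seed = seed)
    tab$x_um <- runif(150, 20, 70)
    tab$y_um <- runif(150, 20, 70)
    pr <- make_profiles(tab, geom, sectioning_design(4, 3L, 2L, "all"),
                        visibility_floor = 0)
    e <- estimate_density(pr)
    expect_equal(e$density_corrected,
                 e$density_uncorrected * e$thickness /
                   (e$thickness + e$dbar_um), tolerance = 1e-12)
    # monodisperse: uncorrected / corrected = (t + D)/t exactly
    expect_equal(e$density_uncorrected / e$density_corrected,
                 (4 + e$dbar_um) / 4, tolerance = 1e-12)
    expect_equal(e$dbar_um, 34, tolerance = 1e-9)
  }
})

test_that("an empty section set yields zero density, not an error", {
  geom <- plane_geom(c(20L, 20L, 60L))
  empty <- data.frame(id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0),
                      diameter_um = numeric(0))
  pr <- make_profiles(empty, geom, sectioning_design(4, 1L, 1L, "all"))
  e <- estimate_density(pr)
  expect_equal(e$density_corrected, 0)
  expect_equal(e$density_uncorrected, 0)
  expect_true(is.na(e$dbar_um))
})

test_that("the corrected count is unbiased for monodisperse spheres", {
  geom <- plane_geom(c(60L, 60L, 460L))
  ratios <- vapply(1:10, function(s) {
    sp <- phantom_spec(dims = c(60L, 60L, 460L), parent_intensity = 4000,
                       mean_cluster_size = 1, cluster_sd = 10,
                       depth_law = list(dist = "uniform", min = 25,
                                        max = 950),
                       diameter_law = list(median = 36, sigma = 0),
                       min_gap = 0.5, seed = s)
    tr <- generate_phantom(sp, rasterize = FALSE)
    pr <- make_profiles(tr$oocytes, geom,
                        sectioning_design(4, 1L, 1L, "all"),
                        visibility_floor = 0)
    estimate_density(pr)$n_hat / nrow(tr$oocytes)
  }, numeric(1))
  expect_gt(mean(ratios), 0.95)
  expect_lt(mean(ratios), 1.05)
})

test_that("sampling start errors are informative and sweeps degenerate sanely", {
  geom <- plane_geom(c(20L, 20L, 60L))
  tab <- mono_table(10, 20, 100, seed = 1)
  expect_error(make_profiles(tab, geom,
                             sectioning_design(4, 1L, 500L, "all")),
               "34 sections")
  # k = 1, all sections: a single degenerate start, CV = 0
  os <- offset_sweep(tab, geom, thickness = 4, interval = 1L,
                     n_analyzed = 34L)
  expect_identical(nrow(os$estimates), 1L)
  expect_equal(unname(os$summary["cv"]), 0)
})

test_that("interval sweep at k = 1 reproduces the all-sections estimate", {
  geom <- plane_geom(c(40L, 40L, 200L))
  tab <- mono_table(120, 30, 400, seed = 3)
  tab$x_um <- runif(120, 20, 70); tab$y_um <- runif(120, 20, 70)
  sw <- interval_sweep(tab, geom, thickness = 4, k_range = 1:5,
                       visibility_floor = 0)
  pr <- make_profiles(tab, geom, sectioning_design(4, 1L, 1L, "all"),
                      visibility_floor = 0)
  expect_equal(sw$density_corrected[sw$k == 1],
               estimate_density(pr)$density_corrected)
  expect_equal(sw$rel_dev[sw$k == 1], 0)
})

test_that("right-skewed diameters make the correction overshoot", {
  # Dbar from the largest decile exceeds the typical diameter, so the
  # corrected density undershoots the 3D truth
  dirs <- vapply(1:5, function(s) {
    sp <- phantom_spec(dims = c(120L, 120L, 460L), parent_intensity = 3000,
                       mean_cluster_size = 1, cluster_sd = 10,
                       depth_law = list(dist = "uniform", min = 25,
                                        max = 950),
                       diameter_law = list(median = 31, sigma = 0.15),
                       min_gap = 0.5, seed = s)
    tr <- generate_phantom(sp, rasterize = FALSE)
    geom <- build_cortex(tr$epithelium_mask, tr$tissue_mask, sp$voxel_size)
    pr <- make_profiles(tr$oocytes, geom,
                        sectioning_design(4, 1L, 1L, "all", axis = "x"),
                        visibility_floor = 0)
    estimate_density(pr)$density_corrected - density_3d(tr$oocytes, geom)
  }, numeric(1))
  expect_true(all(dirs < 0))
})

test_that("a zero-oocyte phantom compares strategies without errors", {
  geom <- plane_geom(c(60L, 60L, 100L))
  empty <- data.frame(id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0),
                      diameter_um = numeric(0))
  cs <- compare_strategies(empty, geom, interval = 2L, five_start = 2L,
                           n_five = 5L, axis = "x")
  expect_equal(cs$density_per_mm3, c(0, 0, 0))
  expect_equal(cs$rel_error, c(0, 0, 0))
})
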