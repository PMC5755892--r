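test_that("phantom truth matches the analytic ellipsoid volume", {
  # semi-axes (20, 15, 12) mm: 4/3*pi*abc = 15.0796 cm^3
  spec <- phantom_spec(
    grid_shape = c(100L, 200L, 200L), spacing_mm = c(0.5, 0.35, 0.35),
    right = phantom_cavity("right", center_mm = c(25, 35, 17),
                           semi_axes_mm = c(20, 15, 12)),
    left = phantom_cavity("left", center_mm = c(25, 35, 53),
                          semi_axes_mm = c(20, 15, 12)),
    noise_sd_hu = 0, include_decoy = FALSE)
  ph <- generate_phantom(spec)
  analytic <- 4 / 3 * pi * 20 * 15 * 12 / 1000
  expect_equal(ph$truth$table$cavity_cm3, rep(analytic, 2))
  # voxel counts of the truth labels agree with the analytic volume to 3%
  m <- compute_volumes(ph$truth$labels)
  for (i in 1:2)
    expect_lt(abs(m$total_volume_cm3[i] - analytic) / analytic, 0.03)
})

test_that("truth voxelisation error shrinks to 1% at half spacing", {
  mk <- function(scale) {
    phantom_spec(
      grid_shape = as.integer(c(60, 160, 160) * scale),
      spacing_mm = c(0.5, 0.35, 0.35) / scale,
      right = phantom_cavity("right", center_mm = c(15, 28, 12),
                             semi_axes_mm = c(9, 12, 8)),
      left = phantom_cavity("left", center_mm = c(15, 28, 44),
                            semi_axes_mm = c(9, 12, 8)),
      noise_sd_hu = 0, include_decoy = FALSE)
  }
  analytic <- 4 / 3 * pi * 9 * 12 * 8 / 1000
  err <- vapply(c(1, 2), function(s) {
    m <- compute_volumes(generate_phantom(mk(s))$truth$labels)
    max(abs(m$total_volume_cm3 - analytic) / analytic)
  }, numeric(1))
  expect_lt(err[1], 0.03)
  expect_lt(err[2], 0.01)
})

test_that("mucosal lining and fluid reduce the analytic air volume", {
  spec <- small_spec(noise_sd_hu = 0, mucosa_thickness_mm = 2)
  ph <- generate_phantom(spec)
  inner <- 4 / 3 * pi * prod(c(8, 11, 7) - 2) / 1000
  expect_equal(ph$truth$table$air_cm3, rep(inner, 2), tolerance = 1e-12)
  # the voxelised involvement shell is within 10% of the analytic shell
  m <- compute_volumes(ph$truth$labels)
  shell <- ph$truth$table$involvement_cm3[1]
  expect_lt(max(abs(m$involvement_volume_cm3 - shell) / shell), 0.10)
  # fully fluid-filled cavity has zero air
  full <- generate_phantom(small_spec(noise_sd_hu = 0,
                                      fluid_fill_fraction = 1))
  expect_equal(full$truth$table$air_cm3, c(0, 0), tolerance = 1e-12)
})

test_that("the dependent fluid layer matches the analytic cap volume", {
  spec <- small_spec(noise_sd_hu = 0, fluid_fill_fraction = 0.3)
  ph <- generate_phantom(spec)
  tr <- ph$truth$table
  expect_true(all(tr$air_cm3 < tr$cavity_cm3))
  expect_true(all(tr$air_cm3 > 0))
  # voxelised air count vs analytic air volume
  m <- compute_volumes(ph$truth$labels)
  expect_lt(max(abs(m$air_volume_cm3 - tr$air_cm3) / tr$air_cm3), 0.03)
})

test_that("phantom generation is deterministic for a fixed seed", {
  a <- generate_phantom(small_spec(rng_seed = 9))
  b <- generate_phantom(small_spec(rng_seed = 9))
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$labels$labels, b$truth$labels$labels)
  d <- generate_phantom(small_spec(rng_seed = 10))
  expect_false(identical(a$volume$voxels, d$volume$voxels))
})

test_that("tissue classes stay clear of the band edges under noise", {
  spec <- small_spec()
  # air vs -200 and mucosa/soft vs both edges, in units of the noise SD
  expect_gte((-200 - spec$hu_air) / spec$noise_sd_hu, 6)
  expect_gte((spec$hu_mucosa - -200) / spec$noise_sd_hu, 6)
  expect_gte((150 - spec$hu_mucosa) / spec$noise_sd_hu, 6)
  expect_gte((150 - spec$hu_soft) / spec$noise_sd_hu, 6)
  expect_gte((spec$hu_bone - 150) / spec$noise_sd_hu, 6)
})

test_that("spec invariants are enforced with informative errors", {
  expect_error(phantom_spec(fluid_fill_fraction = 1.5), "fluid")
  expect_error(phantom_spec(noise_sd_hu = -1), "noise")
  expect_error(phantom_spec(mucosa_thickness_mm = 12), "semi-axis")
  expect_error(
    phantom_spec(right = phantom_cavity("right",
                                        center_mm = c(5, 44.8, 21.3))),
    "fit inside")
  expect_error(
    phantom_spec(wall_thickness_mm = 20), "wall_thickness")
})

test_that("cohorts are reproducible and cover the configured ranges", {
  s1 <- cohort_specs(8, small_spec(), rng_seed = 3)
  s2 <- cohort_specs(8, small_spec(), rng_seed = 3)
  expect_identical(s1, s2)
  s3 <- cohort_specs(8, small_spec(), rng_seed = 4)
  expect_false(identical(s1, s3))
  # draws actually vary between exams and stay inside the ranges
  v <- cohort_variation()
  muc <- vapply(s1, function(s) s$mucosa_thickness_mm, numeric(1))
  expect_gt(stats::sd(muc), 0)
  expect_true(all(muc >= v$mucosa_thickness_mm[1] &
                    muc <= v$mucosa_thickness_mm[2]))
  scales <- vapply(s1, function(s)
    s$right$semi_axes_mm[1] / small_spec()$right$semi_axes_mm[1],
    numeric(1))
  expect_true(all(scales >= v$semi_axis_scale[1] &
                    scales <= v$semi_axis_scale[2]))
})

test_that("zero-width variation reproduces the base phantom exactly", {
  base <- small_spec(noise_sd_hu = 0)
  cohort <- generate_cohort(1, base, zero_variation(base), rng_seed = 5)
  direct <- generate_phantom(base)
  expect_identical(cohort[[1]]$volume$voxels, direct$volume$voxels)
  expect_equal(cohort[[1]]$truth$table, direct$truth$table)
})

test_that("cohort contract: n exams yield 2n sinus truth rows", {
  cohort <- generate_cohort(3, small_spec(), rng_seed = 6)
  expect_length(cohort, 3)
  rows <- do.call(rbind, lapply(cohort, function(x) x$truth$table))
  expect_equal(nrow(rows), 6)
  expect_true(all(rows$air_cm3 <= rows$cavity_cm3 + 1e-12))
})

test_that("empty variation ranges are rejected", {
  v <- cohort_variation()
  v$mucosa_thickness_mm <- c(2, 1)
  expect_error(cohort_specs(2, small_spec(), v), "empty")
  v2 <- cohort_variation()
  v2$semi_axis_scale <- numeric(0)
  expect_error(cohort_specs(2, small_spec(), v2), "2 finite")
})
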