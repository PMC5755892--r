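test_that("bone thresholding uses a closed lower bound at 150 HU", {
  sl <- matrix(c(-1000, 100, 200, 500), 2, 2, byrow = TRUE)
  expect_equal(threshold_bone(sl, 150),
               matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2, byrow = TRUE))
  expect_false(any(threshold_bone(matrix(-1000, 4, 4))))
  expect_true(threshold_bone(matrix(150, 1, 1), 150)[1, 1])
})

test_that("morphological opening matches the brute-force oracle", {
  kern <- EBImage::makeBrush(3, "disc")
  off <- bf_offsets(kern)
  # radius 0, min area 0 is the identity
  set.seed(21)
  m0 <- matrix(runif(100) > 0.5, 10, 10)
  expect_equal(morphological_open(m0, 0, 0), m0)
  # a single isolated pixel is erased
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_false(any(morphological_open(single, 1, 0)))
  # random masks: exact agreement with brute-force set morphology,
  # subset of the dilation of the erosion, and idempotence
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(runif(32 * 32) > 0.4, 32, 32)
    got <- morphological_open(m, 1, 0)
    oracle <- bf_open(m, off)
    expect_equal(got, oracle)
    expect_true(all(got <= bf_dilate(bf_erode(m, off), off)))
    expect_equal(morphological_open(got, 1, 0), got)
  }
  expect_error(morphological_open(m0, -1), ">= 0")
})

test_that("small components below the area threshold are removed", {
  m <- matrix(FALSE, 20, 20)
  m[2:10, 2:10] <- TRUE   # 81 px
  m[15:16, 15:16] <- TRUE # 4 px
  got <- morphological_open(m, 0, min_component_area_mm2 = 10,
                            spacing_mm = c(1, 1))
  expect_true(all(got[2:10, 2:10]))
  expect_false(any(got[15:16, 15:16]))
})

test_that("watershed partitions completely and separates HU wells", {
  sl <- matrix(0, 40, 40)
  sl[10:18, 8:16] <- -1000
  sl[10:18, 24:32] <- -1000
  sl[, 19:21] <- 400
  b <- watershed_partition(sl, smooth_sigma_px = 0)
  # complete partition: every pixel labelled, labels disjoint by storage
  expect_true(all(b >= 1L))
  expect_equal(sum(tabulate(b)), length(b))
  # oracle: each connected low-HU component maps onto one distinct basin
  wells <- EBImage::bwlabel((sl < -500) * 1)
  lab1 <- unique(as.vector(b[wells == 1]))
  lab2 <- unique(as.vector(b[wells == 2]))
  expect_length(lab1, 1)
  expect_length(lab2, 1)
  expect_false(lab1 == lab2)
})

test_that("a constant slice yields a single basin", {
  u <- watershed_partition(matrix(7, 25, 25), smooth_sigma_px = 0)
  expect_equal(max(u), 1L)
})

test_that("watershed partition property holds on random slices", {
  for (seed in 1:4) {
    set.seed(seed)
    sl <- matrix(rnorm(50 * 50, sd = 300), 50, 50)
    b <- watershed_partition(sl, smooth_sigma_px = 1, merge_depth_hu = 100)
    expect_true(all(b >= 1L))
    expect_equal(sum(tabulate(b)), length(b))
  }
})

test_that("rule-based selection keeps mirrored sinus basins, drops noise", {
  # constructed slice: two mirrored ellipses + small noise blobs + a
  # midline channel, 0.5 mm pixels on a 128x128 grid
  sl <- matrix(40, 128, 128)
  yc <- (seq_len(128) - 0.5) * 0.5
  xc <- (seq_len(128) - 0.5) * 0.5
  put_ellipse <- function(sl, cy, cx, ry, rx, hu) {
    q <- outer(((yc - cy) / ry)^2, ((xc - cx) / rx)^2, "+")
    sl[q <= 1] <- hu
    sl
  }
  # bone-rimmed mirrored cavities, ~600 mm2 each
  sl <- put_ellipse(sl, 32, 18, 18, 14, 700)
  sl <- put_ellipse(sl, 32, 18, 16, 12, -1000)
  sl <- put_ellipse(sl, 32, 46, 18, 14, 700)
  sl <- put_ellipse(sl, 32, 46, 16, 12, -1000)
  sl[60:64, 62:66] <- -1000                       # midline noise blob
  sl[10:11, 20:21] <- -1000                       # 1 mm2 speck
  basins <- watershed_partition(sl, smooth_sigma_px = 0)
  cands <- basin_candidates(basins, c(0.5, 0.5))
  sel <- select_sinus_basins(cands, rule_params(), 64, 64)
  expect_false(is.null(sel$right))
  expect_false(is.null(sel$left))
  # oracle: exhaustive evaluation of the individual rules over all basins
  rules <- rule_params()
  lat <- ifelse(cands$side == "right", cands$centroid_col_mm / 64,
                (64 - cands$centroid_col_mm) / 64)
  ax <- cands$centroid_row_mm / 64
  pass <- cands$area_mm2 >= rules$min_area_mm2 &
    cands$area_mm2 <= rules$max_area_mm2 &
    lat >= rules$lateral_band[1] & lat <= rules$lateral_band[2] &
    ax >= rules$axial_band[1] & ax <= rules$axial_band[2] &
    !is.na(cands$solidity) & cands$solidity >= rules$min_solidity
  for (side in c("right", "left")) {
    surv <- cands[pass & cands$side == side, ]
    expect_equal(sel[[side]]$basin_id,
                 surv$basin_id[which.max(surv$area_mm2)])
  }
  # the selected basins are the two big ellipses, ~600 mm2 each
  expect_gt(sel$right$area_mm2, 400)
  expect_gt(sel$left$area_mm2, 400)
})

test_that("a midline basin is rejected by the lateral band", {
  cands <- tibble::tibble(
    basin_id = 1L, n_px = 400L, area_mm2 = 400,
    centroid_row_mm = 32, centroid_col_mm = 32.2,
    solidity = 0.95, side = "left")
  sel <- select_sinus_basins(cands, rule_params(), 64, 64)
  expect_null(sel$right)
  expect_null(sel$left)
})

test_that("asymmetric pairs are rejected on seed slices only", {
  cands <- tibble::tibble(
    basin_id = 1:2, n_px = c(1200L, 300L), area_mm2 = c(600, 150),
    centroid_row_mm = c(32, 32), centroid_col_mm = c(46, 18),
    solidity = c(0.95, 0.95), side = c("left", "right"))
  # ratio 4 > 3: pair rejected when symmetry is enforced
  sel <- select_sinus_basins(cands, rule_params(), 64, 64,
                             enforce_symmetry = TRUE)
  expect_null(sel$right)
  expect_null(sel$left)
  # during propagation sides are assessed independently
  sel2 <- select_sinus_basins(cands, rule_params(), 64, 64,
                              enforce_symmetry = FALSE)
  expect_equal(sel2$left$basin_id, 1L)
  expect_equal(sel2$right$basin_id, 2L)
})

test_that("propagation recovers the cavity slice span from the middle", {
  spec <- small_spec(noise_sd_hu = 10, rng_seed = 5)
  ph <- generate_phantom(spec)
  regions <- propagate_sinus(ph$volume)
  expect_false(is.null(regions$right))
  expect_false(is.null(regions$left))
  expect_equal(regions$right$seed_slice, floor(40 / 2) + 1L)
  # analytic span: slices whose cavity cross-section is at least the
  # rule area minimum
  cen_z <- 12; semi <- c(8, 11, 7); dz <- 0.6
  zc <- (seq_len(40) - 0.5) * dz
  area <- pi * semi[2] * semi[3] * pmax(0, 1 - ((zc - cen_z) / semi[1])^2)
  expected <- range(which(area >= rule_params()$min_area_mm2))
  for (side in c("right", "left")) {
    expect_lte(abs(regions[[side]]$z_start - expected[1]), 1)
    expect_lte(abs(regions[[side]]$z_end - expected[2]), 1)
    zs <- as.integer(names(regions[[side]]$slices))
    expect_equal(sort(zs), seq(min(zs), max(zs)))  # contiguous
    expect_true(all(lengths(regions[[side]]$slices) > 0))
  }
})

test_that("segmentation fails cleanly on cavity-free volumes", {
  spec <- phantom_spec(grid_shape = c(24L, 64L, 64L),
                       spacing_mm = c(0.6, 0.5, 0.5),
                       right = phantom_cavity("right", present = FALSE),
                       left = phantom_cavity("left", present = FALSE),
                       include_decoy = FALSE, noise_sd_hu = 10)
  ph <- generate_phantom(spec)
  expect_error(propagate_sinus(ph$volume),
               class = "sinusvol_segmentation_failure")
})

test_that("a single cavity is recovered on its own side", {
  spec <- small_spec(noise_sd_hu = 10, rng_seed = 6)
  spec$right$present <- FALSE
  ph <- generate_phantom(spec)
  regions <- propagate_sinus(ph$volume)
  expect_null(regions$right)
  expect_false(is.null(regions$left))
})

test_that("air/involvement banding follows the HU bands", {
  # region HU values {-800, -50, 30} -> 1 air voxel, 2 involvement
  vol <- ct_volume(array(40, c(3, 4, 4)), c(1, 1, 1))
  vol$voxels[2, 1, 1:3] <- c(-800, -50, 30)
  region <- list(side = "right",
                 slices = list(`2` = c(1L, 5L, 9L)),  # column-major idx
                 z_start = 2L, z_end = 2L, seed_slice = 2L)
  cls <- classify_air_involvement(region, vol)
  expect_length(cls$air[["2"]], 1)
  expect_length(cls$involvement[["2"]], 2)
  # band edges: -200 is air (closed band), 150 is excluded bone
  vol$voxels[2, 1, 1:3] <- c(-200, -1300, 150)
  cls2 <- classify_air_involvement(region, vol)
  expect_equal(cls2$air[["2"]], 1L)
  expect_length(cls2$involvement[["2"]], 0)
})

test_that("air and involvement are disjoint subsets of the region", {
  ph <- generate_phantom(small_spec(noise_sd_hu = 15, rng_seed = 7,
                                    mucosa_thickness_mm = 1.5))
  regions <- propagate_sinus(ph$volume)
  cls <- classify_air_involvement(regions$right, ph$volume)
  for (z in names(cls$air)) {
    expect_length(intersect(cls$air[[z]], cls$involvement[[z]]), 0)
    expect_true(all(c(cls$air[[z]], cls$involvement[[z]]) %in%
                      regions$right$slices[[z]]))
  }
})

test_that("raising the upper air bound never shrinks the air class", {
  ph <- generate_phantom(small_spec(noise_sd_hu = 20, rng_seed = 8,
                                    mucosa_thickness_mm = 1))
  regions <- propagate_sinus(ph$volume)
  counts <- vapply(c(-400, -200, -50, 100), function(hi) {
    p <- segmentation_params(air_hu_high = hi)
    cls <- classify_air_involvement(regions$left, ph$volume, p)
    sum(lengths(cls$air))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("segmentation is mirror-consistent under left-right reflection", {
  ph <- generate_phantom(small_spec(noise_sd_hu = 15, rng_seed = 4))
  seg <- segment_sinuses(ph$volume)
  refl <- ph$volume
  refl$voxels <- refl$voxels[, , dim(refl$voxels)[3]:1]
  segr <- segment_sinuses(refl)
  cnt <- tabulate(seg$label_map$labels, 4)
  cntr <- tabulate(segr$label_map$labels, 4)
  # sides swap: right (codes 1,2) <-> left (codes 3,4)
  expect_equal(cnt[1:2], cntr[3:4])
  expect_equal(cnt[3:4], cntr[1:2])
})

test_that("noise-free phantom region recovers the analytic volume to 3%", {
  ph <- generate_phantom(small_spec(noise_sd_hu = 0))
  seg <- segment_sinuses(ph$volume)
  m <- compute_volumes(seg$label_map)
  analytic <- 4 / 3 * pi * 8 * 11 * 7 / 1000
  for (i in seq_len(nrow(m)))
    expect_lt(abs(m$total_volume_cm3[i] - analytic) / analytic, 0.03)
})

test_that("parameter constructors validate their invariants", {
  expect_error(segmentation_params(air_hu_low = -100, air_hu_high = -200),
               "air_hu_low")
  expect_error(segmentation_params(opening_radius_px = -1), ">= 0")
  expect_error(rule_params(min_area_mm2 = 10, max_area_mm2 = 5), "below")
  expect_error(rule_params(min_solidity = 1.2), "0, 1")
  expect_error(rule_params(symmetry_area_ratio_max = 0.5), ">= 1")
})
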