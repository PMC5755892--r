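# Small phantom used throughout the suite: 40 x 128 x 128 grid at
# (0.6, 0.5, 0.5) mm, cavities with semi-axes (8, 11, 7) mm. Fast to
# generate and segment while exercising every pipeline stage.
small_spec <- function(noise_sd_hu = 15, rng_seed = 1, ...) {
  phantom_spec(
    grid_shape = c(40L, 128L, 128L),
    spacing_mm = c(0.6, 0.5, 0.5),
    right = phantom_cavity("right", center_mm = c(12, 32, 18),
                           semi_axes_mm = c(8, 11, 7)),
    left = phantom_cavity("left", center_mm = c(12, 32, 46),
                          semi_axes_mm = c(8, 11, 7)),
    noise_sd_hu = noise_sd_hu, rng_seed = rng_seed, ...)
}

# degenerate variation: every draw equals the base spec value
zero_variation <- function(base = small_spec()) {
  list(semi_axis_scale = c(1, 1), center_jitter_mm = c(0, 0, 0),
       mucosa_thickness_mm = rep(base$mucosa_thickness_mm, 2),
       fluid_fill_fraction = rep(base$fluid_fill_fraction, 2))
}

# brute-force binary morphology on small grids, used as the independent
# oracle for morphological_open
bf_offsets <- function(kern) {
  ctr <- (dim(kern) + 1) / 2
  w <- which(kern > 0, arr.ind = TRUE)
  cbind(w[, 1] - ctr[1], w[, 2] - ctr[2])
}

# out-of-bounds neighbours count as foreground for erosion and as
# background for dilation (replicate-style padding, as in EBImage)
bf_erode <- function(mask, off) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    rr <- r + off[, 1]; cc <- c + off[, 2]
    inb <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
    out[r, c] <- all(mask[cbind(rr[inb], cc[inb])])
  }
  out
}

bf_dilate <- function(mask, off) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    rr <- r - off[, 1]; cc <- c - off[, 2]
    inb <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
    out[r, c] <- any(mask[cbind(rr[inb], cc[inb])])
  }
  out
}

bf_open <- function(mask, off) bf_dilate(bf_erode(mask, off), off)

# voxelised ellipsoid label map (air class, right side) for volumetry tests
voxelised_ellipsoid <- function(semi, spacing, grid, center = grid * spacing / 2) {
  arr <- array(0L, grid)
  zc <- (seq_len(grid[1]) - 0.5) * spacing[1]
  yc <- (seq_len(grid[2]) - 0.5) * spacing[2]
  xc <- (seq_len(grid[3]) - 0.5) * spacing[3]
  q2 <- outer(((yc - center[2]) / semi[2])^2,
              ((xc - center[3]) / semi[3])^2, "+")
  for (s in seq_len(grid[1])) {
    u2 <- ((zc[s] - center[1]) / semi[1])^2
    arr[s, , ] <- (q2 + u2 <= 1) * 1L
  }
  label_map(arr, spacing)
}
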