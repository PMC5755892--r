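#' Synthetic head-CT phantom specification
#'
#' Parametric description of a head-like CT volume: two quasi-ellipsoidal
#' air cavities (the maxillary sinuses) enclosed in bone shells, embedded
#' in soft tissue, with an optional mucosal lining, an optional dependent
#' fluid layer, a midline low-HU "nasal cavity" decoy channel, additive
#' Gaussian HU noise, and anisotropic voxel spacing. Cavity volumes are
#' analytically known, which makes the phantom an exact oracle for the
#' segmentation pipeline.
#'
#' @param grid_shape integer triple `(n_slices, n_rows, n_cols)`.
#' @param spacing_mm numeric triple `(slice, row, column)` spacing in mm.
#' @param right,left per-side cavity description: a list with `present`,
#'   `center_mm` (z, row, col), `semi_axes_mm` (z, row, col) and
#'   `rotation_deg` (in-plane rotation about the slice axis; the slice
#'   axis stays principal so the dependent-fluid cap volume remains
#'   closed-form).
#' @param wall_thickness_mm bone shell thickness.
#' @param hu_air,hu_soft,hu_bone,hu_mucosa tissue HU values. Defaults keep
#'   the classes separated by the classification band edges (-200 HU,
#'   150 HU).
#' @param mucosa_thickness_mm nominal lining thickness; the lining is the
#'   shell between the cavity ellipsoid and an inner ellipsoid with
#'   semi-axes reduced by this amount.
#' @param fluid_fill_fraction fraction (0-1) of the cavity's slice extent,
#'   from the most inferior slice, filled with fluid at `hu_mucosa`.
#' @param noise_sd_hu SD of additive Gaussian noise in HU.
#' @param rng_seed seed for the noise draw.
#' @param include_decoy add the midline nasal-cavity decoy channel.
#'
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(80L, 256L, 256L),
                         spacing_mm = c(0.5, 0.35, 0.35),
                         right = phantom_cavity(side = "right"),
                         left = phantom_cavity(side = "left"),
                         wall_thickness_mm = 1.5,
                         hu_air = -1000, hu_soft = 40, hu_bone = 700,
                         hu_mucosa = 30,
                         mucosa_thickness_mm = 0,
                         fluid_fill_fraction = 0,
                         noise_sd_hu = 15,
                         rng_seed = 1L,
                         include_decoy = TRUE) {
  spec <- structure(
    list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
         right = right, left = left,
         wall_thickness_mm = wall_thickness_mm,
         hu_air = hu_air, hu_soft = hu_soft, hu_bone = hu_bone,
         hu_mucosa = hu_mucosa,
         mucosa_thickness_mm = mucosa_thickness_mm,
         fluid_fill_fraction = fluid_fill_fraction,
         noise_sd_hu = noise_sd_hu, rng_seed = as.integer(rng_seed),
         include_decoy = include_decoy),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Default cavity geometry for one side
#'
#' @param side `"right"` or `"left"`; the default centres mirror across
#'   the sagittal midline of the default grid.
#' @param center_mm,semi_axes_mm,rotation_deg,present override fields.
#' @return A list describing one cavity.
#' @export
phantom_cavity <- function(side = c("right", "left"), center_mm = NULL,
                           semi_axes_mm = c(14, 20, 11.5),
                           rotation_deg = 0, present = TRUE) {
  side <- match.arg(side)
  if (is.null(center_mm))
    center_mm <- c(20, 44.8, if (side == "right") 21.3 else 68.3)
  list(present = present, center_mm = center_mm,
       semi_axes_mm = semi_axes_mm, rotation_deg = rotation_deg)
}

validate_phantom_spec <- function(spec) {
  extent <- spec$grid_shape * spec$spacing_mm
  if (spec$fluid_fill_fraction < 0 || spec$fluid_fill_fraction > 1)
    stop("fluid_fill_fraction must lie in [0, 1]", call. = FALSE)
  if (spec$noise_sd_hu < 0)
    stop("noise_sd_hu must be >= 0", call. = FALSE)
  if (!(spec$hu_air < -200 && -200 <= spec$hu_mucosa))
    stop("hu_air must be below -200 and hu_mucosa at or above it",
         call. = FALSE)
  if (!(spec$hu_soft < 150 && 150 <= spec$hu_bone))
    stop("hu_soft must be below 150 and hu_bone at or above it",
         call. = FALSE)
  for (side in c("right", "left")) {
    cav <- spec[[side]]
    if (!isTRUE(cav$present)) next
    if (any(cav$semi_axes_mm <= spec$wall_thickness_mm))
      stop("semi_axes_mm must exceed wall_thickness_mm (", side, ")",
           call. = FALSE)
    if (spec$mucosa_thickness_mm >= min(cav$semi_axes_mm))
      stop("mucosa_thickness_mm must be below every semi-axis (", side,
           ")", call. = FALSE)
    # in-plane reach is exact for unrotated cavities, conservative otherwise
    inplane <- if (cav$rotation_deg %% 180 == 0) cav$semi_axes_mm[2:3]
               else rep(max(cav$semi_axes_mm[2:3]), 2)
    reach <- c(cav$semi_axes_mm[1], inplane) + spec$wall_thickness_mm
    if (any(cav$center_mm - reach < 0) ||
        any(cav$center_mm + reach > extent))
      stop("cavity (including wall) does not fit inside the grid (", side,
           ": center_mm/semi_axes_mm)", call. = FALSE)
  }
  invisible(spec)
}

ellipsoid_volume_cm3 <- function(semi) 4 / 3 * pi * prod(semi) / 1000

# volume (cm^3) of the part of an axis-aligned-in-z ellipsoid below the
# plane z = z_plane; exact for in-plane-rotated ellipsoids too
ellipsoid_cap_below_cm3 <- function(semi, center_z, z_plane) {
  u <- (z_plane - center_z) / semi[1]
  u <- max(-1, min(1, u))
  semi[1] * semi[2] * semi[3] * pi * (u - u^3 / 3 + 2 / 3) / 1000
}

#' Generate a synthetic head-CT phantom
#'
#' Builds the HU volume described by a [phantom_spec()] together with its
#' analytic ground truth. Voxels are assigned by voxel-centre membership;
#' noise is added after the truth is computed.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` (a [ct_volume()]) and `truth` (a list with
#'   `table`, a tibble of per-side analytic volumes in cm^3, and `labels`,
#'   the ground-truth [label_map()]).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  vox <- array(spec$hu_soft, dim = d)
  labels <- array(0L, dim = d)
  rowc <- (seq_len(d[2]) - 0.5) * sp[2]
  colc <- (seq_len(d[3]) - 0.5) * sp[3]
  Y <- matrix(rowc, d[2], d[3])
  X <- matrix(colc, d[2], d[3], byrow = TRUE)
  zc <- (seq_len(d[1]) - 0.5) * sp[1]
  extent <- d * sp

  if (spec$include_decoy) {
    half_w <- 4
    rim <- spec$wall_thickness_mm
    y0 <- 0.22 * extent[2]; y1 <- 0.80 * extent[2]
    z0 <- 0.15 * extent[1]; z1 <- 0.85 * extent[1]
    midx <- extent[3] / 2
    core2d <- abs(X - midx) <= half_w & Y >= y0 & Y <= y1
    rim2d <- abs(X - midx) <= half_w + rim & Y >= y0 - rim & Y <= y1 + rim
    for (s in seq_len(d[1])) {
      if (zc[s] < z0 - rim || zc[s] > z1 + rim) next
      sl <- vox[s, , ]
      in_core_z <- zc[s] >= z0 && zc[s] <= z1
      sl[rim2d] <- spec$hu_bone
      if (in_core_z) sl[core2d] <- spec$hu_air
      vox[s, , ] <- sl
    }
  }

  rows_tbl <- list()
  for (side in c("right", "left")) {
    cav <- spec[[side]]
    if (!isTRUE(cav$present)) next
    semi <- cav$semi_axes_mm
    cen <- cav$center_mm
    t_muc <- spec$mucosa_thickness_mm
    semi_air <- pmax(semi - t_muc, 0)
    theta <- cav$rotation_deg * pi / 180
    dxm <- X - cen[3]; dym <- Y - cen[2]
    xr <- cos(theta) * dxm + sin(theta) * dym
    yr <- -sin(theta) * dxm + cos(theta) * dym
    q2_cav <- (yr / semi[2])^2 + (xr / semi[3])^2
    q2_wall <- (yr / (semi[2] + spec$wall_thickness_mm))^2 +
      (xr / (semi[3] + spec$wall_thickness_mm))^2
    q2_air <- if (all(semi_air > 0))
      (yr / semi_air[2])^2 + (xr / semi_air[3])^2 else NULL
    z_fluid <- cen[1] - semi[1] + spec$fluid_fill_fraction * 2 * semi[1]
    code_air <- if (side == "right") LABEL_RIGHT_AIR else LABEL_LEFT_AIR
    code_inv <- if (side == "right") LABEL_RIGHT_INV else LABEL_LEFT_INV
    zr <- which(abs(zc - cen[1]) <= semi[1] + spec$wall_thickness_mm)
    for (s in zr) {
      uz_cav <- ((zc[s] - cen[1]) / semi[1])^2
      uz_wall <- ((zc[s] - cen[1]) / (semi[1] + spec$wall_thickness_mm))^2
      in_cav <- q2_cav + uz_cav <= 1
      in_wall <- q2_wall + uz_wall <= 1 & !in_cav
      in_air <- if (!is.null(q2_air) && semi_air[1] > 0)
        q2_air + ((zc[s] - cen[1]) / semi_air[1])^2 <= 1 & in_cav
      else matrix(FALSE, d[2], d[3])
      is_fluid_slice <- zc[s] < z_fluid
      sl <- vox[s, , ]; lb <- labels[s, , ]
      sl[in_wall] <- spec$hu_bone
      sl[in_cav & !in_air] <- spec$hu_mucosa
      lb[in_cav & !in_air] <- code_inv
      if (is_fluid_slice) {
        sl[in_air] <- spec$hu_mucosa
        lb[in_air] <- code_inv
      } else {
        sl[in_air] <- spec$hu_air
        lb[in_air] <- code_air
      }
      vox[s, , ] <- sl; labels[s, , ] <- lb
    }
    v_cav <- ellipsoid_volume_cm3(semi)
    v_air_ell <- if (all(semi_air > 0)) ellipsoid_volume_cm3(semi_air) else 0
    v_fluid <- if (all(semi_air > 0))
      ellipsoid_cap_below_cm3(semi_air, cen[1], z_fluid) else 0
    v_air <- v_air_ell - v_fluid
    rows_tbl[[side]] <- tibble::tibble(
      side = side, cavity_cm3 = v_cav, air_cm3 = v_air,
      involvement_cm3 = max(0, v_cav - v_air))
  }

  if (spec$noise_sd_hu > 0) {
    noise <- withr::with_seed(
      spec$rng_seed,
      array(stats::rnorm(prod(d), sd = spec$noise_sd_hu), dim = d))
    vox <- vox + noise
  }

  list(volume = ct_volume(vox, spacing_mm = sp,
                          patient_orientation = "LPS-aligned"),
       truth = list(table = dplyr::bind_rows(rows_tbl),
                    labels = label_map(labels, sp)))
}

#' Default cohort variation ranges
#'
#' Uniform draw ranges used by [cohort_specs()] and [generate_cohort()]:
#' per-axis semi-axis scale factors, per-dimension centre jitter, mucosal
#' lining thickness and dependent-fluid fill fraction. The defaults give
#' cavity volumes spanning roughly 8-20 cm^3, the range reported for adult
#' maxillary sinuses.
#'
#' @return Named list of ranges.
#' @export
cohort_variation <- function() {
  list(semi_axis_scale = c(0.85, 1.15),
       center_jitter_mm = c(1, 3, 2),
       mucosa_thickness_mm = c(0.5, 2.5),
       fluid_fill_fraction = c(0, 0.25))
}

check_range <- function(r, name, len = 2L) {
  if (length(r) != len || any(!is.finite(r)))
    stop("variation range `", name, "` must have ", len, " finite values",
         call. = FALSE)
  if (len == 2L && r[1] > r[2])
    stop("variation range `", name, "` is empty", call. = FALSE)
  r
}

#' Draw phantom specifications for a synthetic validation cohort
#'
#' @param n_exams number of exams (each contributes two sinuses).
#' @param base_spec a [phantom_spec()] all draws start from.
#' @param variation named list of ranges, see [cohort_variation()].
#' @param rng_seed master seed; the whole cohort is reproducible from it.
#' @return List of `n_exams` [phantom_spec()] objects.
#' @export
cohort_specs <- function(n_exams, base_spec = phantom_spec(),
                         variation = cohort_variation(), rng_seed = 1L) {
  if (n_exams < 1) stop("n_exams must be >= 1", call. = FALSE)
  sc <- check_range(variation$semi_axis_scale, "semi_axis_scale")
  jit <- check_range(variation$center_jitter_mm, "center_jitter_mm", 3L)
  muc <- check_range(variation$mucosa_thickness_mm, "mucosa_thickness_mm")
  flu <- check_range(variation$fluid_fill_fraction, "fluid_fill_fraction")
  withr::with_seed(as.integer(rng_seed), {
    seeds <- sample.int(.Machine$integer.max - 1L, n_exams)
    lapply(seq_len(n_exams), function(i) {
      spec <- base_spec
      spec$rng_seed <- seeds[i]
      spec$mucosa_thickness_mm <- stats::runif(1, muc[1], muc[2])
      spec$fluid_fill_fraction <- stats::runif(1, flu[1], flu[2])
      for (side in c("right", "left")) {
        cav <- spec[[side]]
        if (!isTRUE(cav$present)) next
        cav$semi_axes_mm <- cav$semi_axes_mm *
          stats::runif(3, sc[1], sc[2])
        cav$center_mm <- cav$center_mm +
          stats::runif(3, -jit, jit)
        spec[[side]] <- cav
      }
      validate_phantom_spec(spec)
      spec
    })
  })
}

#' Generate a synthetic validation cohort
#'
#' Materialises every exam drawn by [cohort_specs()]. For large grids
#' prefer iterating over [cohort_specs()] and generating one exam at a
#' time; the draws are identical.
#'
#' @inheritParams cohort_specs
#' @return List of `n_exams` results of [generate_phantom()].
#' @export
generate_cohort <- function(n_exams, base_spec = phantom_spec(),
                            variation = cohort_variation(),
                            rng_seed = 1L) {
  lapply(cohort_specs(n_exams, base_spec, variation, rng_seed),
         generate_phantom)
}
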