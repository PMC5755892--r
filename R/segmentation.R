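#' Rule parameters for sinus basin selection
#'
#' Quantifies the position / shape / symmetry rules used to pick the two
#' maxillary-sinus basins out of a watershed partition. All areas are in
#' mm^2, distances in mm, and bands are fractions of the slice extent.
#'
#' @param min_area_mm2,max_area_mm2 candidate basin area bounds.
#' @param min_solidity minimum basin solidity (area / convex-hull area).
#' @param lateral_band fraction pair of the image width, measured from each
#'   lateral edge, within which a candidate centroid must lie. The default
#'   `(0.05, 0.45)` excludes both the image border and the sagittal
#'   midline, so midline structures (nasal cavity) are rejected.
#' @param axial_band fraction pair of the image height (from the top row)
#'   within which the centroid must lie.
#' @param symmetry_area_ratio_max maximum allowed left/right area ratio
#'   when both sides have a surviving candidate.
#' @param symmetry_centroid_tol_mm maximum distance between one candidate's
#'   centroid and the mirror image of the other's.
#'
#' @return A list of class `rule_params`.
#' @export
rule_params <- function(min_area_mm2 = 50, max_area_mm2 = 3000,
                        min_solidity = 0.6,
                        lateral_band = c(0.05, 0.45),
                        axial_band = c(0.25, 0.85),
                        symmetry_area_ratio_max = 3.0,
                        symmetry_centroid_tol_mm = 15) {
  if (min_area_mm2 >= max_area_mm2)
    stop("min_area_mm2 must be below max_area_mm2", call. = FALSE)
  if (min_solidity < 0 || min_solidity > 1)
    stop("min_solidity must lie in [0, 1]", call. = FALSE)
  if (symmetry_area_ratio_max < 1)
    stop("symmetry_area_ratio_max must be >= 1", call. = FALSE)
  structure(list(min_area_mm2 = min_area_mm2, max_area_mm2 = max_area_mm2,
                 min_solidity = min_solidity, lateral_band = lateral_band,
                 axial_band = axial_band,
                 symmetry_area_ratio_max = symmetry_area_ratio_max,
                 symmetry_centroid_tol_mm = symmetry_centroid_tol_mm),
            class = "rule_params")
}

#' Segmentation parameters
#'
#' All tunables of the per-slice pipeline and the outward propagation.
#' HU bands follow the CT attenuation scale: voxels at or above
#' `bone_threshold_hu` are bone; region voxels within
#' `[air_hu_low, air_hu_high]` are air; region voxels between
#' `air_hu_high` and the bone threshold are involvement (mucosal
#' thickening, cysts, fluid).
#'
#' @param bone_threshold_hu HU at or above which a voxel is bone
#'   (default 150).
#' @param opening_radius_px disk radius of the morphological opening
#'   applied to the bone mask (default 2 px, about 0.6 mm at typical
#'   in-plane spacing).
#' @param min_component_area_mm2 bone-mask components smaller than this are
#'   discarded as noise (default 20).
#' @param air_hu_low,air_hu_high closed HU band classified as air inside a
#'   sinus region (defaults -1200 and -200).
#' @param smooth_sigma_px Gaussian sigma (pixels) applied to the HU slice
#'   before watershed flooding (default 1).
#' @param merge_depth_hu watershed basins whose dynamics (saddle height
#'   above their minimum) are below this are merged during flooding
#'   (default 100 HU); suppresses noise-induced over-segmentation while
#'   keeping air cavities, whose walls rise ~1700 HU, separate.
#' @param overlap_min_dice minimum Dice overlap between the accepted basin
#'   on a new slice and the region on the previous slice (default 0.3).
#' @param seed_search_frac fraction of the stack searched around the middle
#'   slice for a seed when the middle slice itself yields nothing
#'   (default 0.25).
#' @param rule_params a [rule_params()] object.
#'
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(bone_threshold_hu = 150,
                                opening_radius_px = 2,
                                min_component_area_mm2 = 20,
                                air_hu_low = -1200, air_hu_high = -200,
                                smooth_sigma_px = 1,
                                merge_depth_hu = 100,
                                overlap_min_dice = 0.3,
                                seed_search_frac = 0.25,
                                rule_params = sinusvol::rule_params()) {
  if (!(air_hu_low < air_hu_high && air_hu_high < bone_threshold_hu))
    stop("need air_hu_low < air_hu_high < bone_threshold_hu", call. = FALSE)
  if (opening_radius_px < 0)
    stop("opening_radius_px must be >= 0", call. = FALSE)
  if (overlap_min_dice < 0 || overlap_min_dice > 1)
    stop("overlap_min_dice must lie in [0, 1]", call. = FALSE)
  structure(list(bone_threshold_hu = bone_threshold_hu,
                 opening_radius_px = as.integer(opening_radius_px),
                 min_component_area_mm2 = min_component_area_mm2,
                 air_hu_low = air_hu_low, air_hu_high = air_hu_high,
                 smooth_sigma_px = smooth_sigma_px,
                 merge_depth_hu = merge_depth_hu,
                 overlap_min_dice = overlap_min_dice,
                 seed_search_frac = seed_search_frac,
                 rule_params = rule_params),
            class = "segmentation_params")
}

#' Bone thresholding of one slice
#'
#' @param slice_hu 2D numeric matrix of HU values.
#' @param bone_threshold_hu threshold; voxels with `HU >=` threshold are
#'   marked bone (closed lower bound).
#' @return Logical matrix, `TRUE` on bone.
#' @export
threshold_bone <- function(slice_hu, bone_threshold_hu = 150) {
  stopifnot(is.matrix(slice_hu))
  slice_hu >= bone_threshold_hu
}

#' Morphological opening with small-component removal
#'
#' Opening (erosion then dilation) with a disk structuring element,
#' followed by removal of connected components smaller than
#' `min_component_area_mm2`, to clear noise speckle from the bone mask.
#'
#' @param mask logical matrix.
#' @param opening_radius_px disk radius in pixels; 0 skips the opening.
#' @param min_component_area_mm2 area threshold; 0 keeps everything.
#' @param spacing_mm length-2 (row, column) pixel spacing in mm.
#' @return Logical matrix.
#' @export
morphological_open <- function(mask, opening_radius_px = 2,
                               min_component_area_mm2 = 20,
                               spacing_mm = c(1, 1)) {
  if (opening_radius_px < 0)
    stop("opening_radius_px must be >= 0", call. = FALSE)
  m <- mask * 1
  if (opening_radius_px > 0) {
    kern <- EBImage::makeBrush(2L * as.integer(opening_radius_px) + 1L,
                               shape = "disc")
    m <- EBImage::opening(m, kern)
  }
  if (min_component_area_mm2 > 0 && any(m > 0)) {
    lab <- EBImage::bwlabel(m)
    px_area <- prod(spacing_mm[1:2])
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes * px_area < min_component_area_mm2)
    if (length(drop)) m[lab %in% drop] <- 0
  }
  m > 0
}

#' Watershed partition of one slice
#'
#' Floods the Gaussian-smoothed HU landscape so that air cavities (deep HU
#' minima) become basins and bone walls become ridges. The cleaned bone
#' mask is imposed as barrier pixels that flood last and are assigned to an
#' adjacent basin, so the result is a complete partition: every pixel
#' carries exactly one basin label.
#'
#' @param slice_hu 2D numeric HU matrix.
#' @param bone_mask optional logical matrix of barrier (bone) pixels.
#' @param smooth_sigma_px Gaussian sigma in pixels (0 = no smoothing).
#' @param merge_depth_hu basins with dynamics below this merge during
#'   flooding.
#' @return Integer matrix of basin labels (1..K).
#' @export
watershed_partition <- function(slice_hu, bone_mask = NULL,
                                smooth_sigma_px = 1, merge_depth_hu = 100) {
  stopifnot(is.matrix(slice_hu))
  surface <- if (smooth_sigma_px > 0)
    EBImage::gblur(slice_hu, sigma = smooth_sigma_px) else slice_hu
  if (is.null(bone_mask))
    bone_mask <- matrix(FALSE, nrow(slice_hu), ncol(slice_hu))
  storage.mode(bone_mask) <- "logical"
  .ws_flood(surface, bone_mask, merge_depth_hu)
}

# Convex-hull solidity of a pixel set: filled-hull pixel count in the
# denominator so a convex raster region scores exactly 1.
basin_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n <= 3L) return(1)
  pts <- cbind(cols, rows)
  hull <- grDevices::chull(pts)
  if (length(hull) < 3L) return(1)
  bnd <- pts[hull, , drop = FALSE]
  rr <- range(rows); cc <- range(cols)
  grid <- cbind(rep(cc[1]:cc[2], each = rr[2] - rr[1] + 1L),
                rep(rr[1]:rr[2], times = cc[2] - cc[1] + 1L))
  inside <- mgcv::in.out(rbind(bnd, bnd[1, ]), grid)
  hull_n <- sum(inside)
  min(1, n / max(n, hull_n))
}

#' Basin candidate features
#'
#' Computes per-basin geometric features used by the rule-based selector.
#'
#' @param basins integer matrix of basin labels from
#'   [watershed_partition()].
#' @param spacing_mm length-2 (row, column) pixel spacing in mm.
#' @param solidity_for optional integer vector of basin ids for which
#'   solidity should be computed (it is the only expensive feature);
#'   `NULL` computes it for all basins.
#' @return A tibble with columns `basin_id`, `n_px`, `area_mm2`,
#'   `centroid_row_mm`, `centroid_col_mm`, `solidity`, `side`.
#' @export
basin_candidates <- function(basins, spacing_mm, solidity_for = NULL) {
  nr <- nrow(basins); nc <- ncol(basins)
  px_area <- prod(spacing_mm[1:2])
  lab <- as.vector(basins)
  k <- max(lab)
  n_px <- tabulate(lab, nbins = k)
  rows <- rep.int(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  sum_r <- rowsum(rows, lab)[, 1]
  sum_c <- rowsum(cols, lab)[, 1]
  ids <- as.integer(rownames(rowsum(rows, lab)))
  cen_r <- numeric(k); cen_c <- numeric(k)
  cen_r[ids] <- sum_r / n_px[ids]
  cen_c[ids] <- sum_c / n_px[ids]
  mid_col <- (nc + 1) / 2
  want <- if (is.null(solidity_for)) seq_len(k) else solidity_for
  sol <- rep(NA_real_, k)
  if (length(want)) {
    idx_by_basin <- split(seq_along(lab), lab)
    for (id in want) {
      ii <- idx_by_basin[[as.character(id)]]
      if (is.null(ii)) next
      sol[id] <- basin_solidity((ii - 1L) %% nr + 1L, (ii - 1L) %/% nr + 1L)
    }
  }
  tibble::tibble(
    basin_id = seq_len(k),
    n_px = n_px,
    area_mm2 = n_px * px_area,
    centroid_row_mm = (cen_r - 0.5) * spacing_mm[1],
    centroid_col_mm = (cen_c - 0.5) * spacing_mm[2],
    solidity = sol,
    side = ifelse(cen_c < mid_col, "right", "left"))
}

# individual (per-side) rules; returns logical vector over candidate rows
passes_side_rules <- function(cands, rules, width_mm, height_mm) {
  lat_frac <- ifelse(cands$side == "right",
                     cands$centroid_col_mm / width_mm,
                     (width_mm - cands$centroid_col_mm) / width_mm)
  ax_frac <- cands$centroid_row_mm / height_mm
  ok <- cands$area_mm2 >= rules$min_area_mm2 &
    cands$area_mm2 <= rules$max_area_mm2 &
    lat_frac >= rules$lateral_band[1] & lat_frac <= rules$lateral_band[2] &
    ax_frac >= rules$axial_band[1] & ax_frac <= rules$axial_band[2]
  # solidity last: only meaningful (and only computed) for survivors
  ok & !is.na(cands$solidity) & cands$solidity >= rules$min_solidity
}

#' Rule-based selection of the sinus basins
#'
#' Applies the position / shape rules per candidate and per side, keeps the
#' largest surviving basin on each side, then (optionally) enforces the
#' symmetry rules on the pair. Symmetry is only checked when both sides
#' have a survivor; a violated pair is rejected outright, which is the
#' behaviour wanted on a seed slice. During propagation sides are assessed
#' independently, so callers pass `enforce_symmetry = FALSE` there.
#'
#' @param cands tibble from [basin_candidates()].
#' @param rules a [rule_params()] object.
#' @param width_mm,height_mm physical slice extent in mm.
#' @param enforce_symmetry check the pairwise symmetry rules.
#' @return List with elements `right` and `left`, each a one-row tibble or
#'   `NULL` when no candidate survives.
#' @export
select_sinus_basins <- function(cands, rules, width_mm, height_mm,
                                enforce_symmetry = TRUE) {
  ok <- passes_side_rules(cands, rules, width_mm, height_mm)
  pick <- function(side) {
    sub <- cands[ok & cands$side == side, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    sub <- sub[order(-sub$area_mm2, sub$basin_id), , drop = FALSE]
    sub[1, , drop = FALSE]
  }
  right <- pick("right"); left <- pick("left")
  if (enforce_symmetry && !is.null(right) && !is.null(left)) {
    ratio <- max(right$area_mm2, left$area_mm2) /
      min(right$area_mm2, left$area_mm2)
    mirror_dist <- sqrt((width_mm - right$centroid_col_mm -
                           left$centroid_col_mm)^2 +
                          (right$centroid_row_mm - left$centroid_row_mm)^2)
    if (ratio > rules$symmetry_area_ratio_max ||
        mirror_dist > rules$symmetry_centroid_tol_mm)
      return(list(right = NULL, left = NULL))
  }
  list(right = right, left = left)
}

dice_overlap <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# threshold -> open -> watershed -> features for one slice, with solidity
# evaluated only for basins that pass the cheap rules on either side
run_slice_pipeline <- function(slice_hu, params, spacing_rc) {
  bone <- threshold_bone(slice_hu, params$bone_threshold_hu)
  cleaned <- morphological_open(bone, params$opening_radius_px,
                                params$min_component_area_mm2, spacing_rc)
  basins <- watershed_partition(slice_hu, cleaned,
                                params$smooth_sigma_px,
                                params$merge_depth_hu)
  cheap <- basin_candidates(basins, spacing_rc, solidity_for = integer(0))
  rules <- params$rule_params
  width_mm <- ncol(slice_hu) * spacing_rc[2]
  height_mm <- nrow(slice_hu) * spacing_rc[1]
  lat_frac <- ifelse(cheap$side == "right",
                     cheap$centroid_col_mm / width_mm,
                     (width_mm - cheap$centroid_col_mm) / width_mm)
  ax_frac <- cheap$centroid_row_mm / height_mm
  need <- cheap$basin_id[cheap$area_mm2 >= rules$min_area_mm2 &
                           cheap$area_mm2 <= rules$max_area_mm2 &
                           lat_frac >= rules$lateral_band[1] &
                           lat_frac <= rules$lateral_band[2] &
                           ax_frac >= rules$axial_band[1] &
                           ax_frac <= rules$axial_band[2]]
  if (length(need)) {
    nr <- nrow(basins)
    lab <- as.vector(basins)
    keep <- lab %in% need
    idx_by_basin <- split(which(keep), lab[keep])
    for (id in need) {
      ii <- idx_by_basin[[as.character(id)]]
      cheap$solidity[id] <- basin_solidity((ii - 1L) %% nr + 1L,
                                           (ii - 1L) %/% nr + 1L)
    }
  }
  list(basins = basins, cands = cheap,
       width_mm = width_mm, height_mm = height_mm)
}

basin_pixels <- function(basins, id) which(as.vector(basins) == id)

#' Middle-slice-outward propagation of the sinus regions
#'
#' Runs the per-slice pipeline on the middle slice of the stack (searching
#' outward over up to `seed_search_frac` of the stack if the middle slice
#' yields nothing), then walks upward and downward from the seed,
#' independently per side. On each new slice a basin is accepted only if it
#' passes the per-side rules and overlaps the previous accepted slice with
#' Dice at least `overlap_min_dice`; the walk stops at the first slice with
#' no acceptable basin.
#'
#' @param volume a [ct_volume()].
#' @param params a [segmentation_params()] object.
#' @return List with elements `right` and `left`; each is `NULL` or a list
#'   with `side`, `slices` (pixel-index sets keyed by slice), `z_start`,
#'   `z_end`, `seed_slice`.
#' @export
propagate_sinus <- function(volume, params = segmentation_params()) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  n <- d[1]
  spacing_rc <- volume$spacing_mm[2:3]
  cache <- new.env(parent = emptyenv())
  pipe <- function(z) {
    key <- as.character(z)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- run_slice_pipeline(volume$voxels[z, , ], params, spacing_rc)
    cache[[key]] <- res
    res
  }
  mid <- floor(n / 2) + 1L
  window <- max(0L, floor(params$seed_search_frac * n))
  offsets <- c(0L, as.vector(rbind(seq_len(window), -seq_len(window))))
  seed <- NULL
  for (off in offsets) {
    z <- mid + off
    if (z < 1L || z > n) next
    p <- pipe(z)
    sel <- select_sinus_basins(p$cands, params$rule_params, p$width_mm,
                               p$height_mm, enforce_symmetry = TRUE)
    if (!is.null(sel$right) || !is.null(sel$left)) {
      seed <- list(z = z, sel = sel, p = p)
      break
    }
  }
  if (is.null(seed))
    rlang::abort(
      paste0("no slice within the seed search window satisfies the ",
             "rule-based system; segmentation failed"),
      class = "sinusvol_segmentation_failure")

  regions <- list(right = NULL, left = NULL)
  for (side in c("right", "left")) {
    hit <- seed$sel[[side]]
    if (is.null(hit)) next
    slices <- list()
    slices[[as.character(seed$z)]] <- basin_pixels(seed$p$basins,
                                                   hit$basin_id)
    for (dir in c(1L, -1L)) {
      prev <- slices[[as.character(seed$z)]]
      z <- seed$z + dir
      while (z >= 1L && z <= n) {
        p <- pipe(z)
        ok <- passes_side_rules(p$cands, params$rule_params, p$width_mm,
                                p$height_mm)
        sub <- p$cands[ok & p$cands$side == side, , drop = FALSE]
        if (nrow(sub) == 0L) break
        sub <- sub[order(-sub$area_mm2, sub$basin_id), , drop = FALSE]
        accepted <- NULL
        for (i in seq_len(nrow(sub))) {
          px <- basin_pixels(p$basins, sub$basin_id[i])
          if (dice_overlap(px, prev) >= params$overlap_min_dice) {
            accepted <- px
            break
          }
        }
        if (is.null(accepted)) break
        slices[[as.character(z)]] <- accepted
        prev <- accepted
        z <- z + dir
      }
    }
    zs <- sort(as.integer(names(slices)))
    regions[[side]] <- list(side = side, slices = slices,
                            z_start = min(zs), z_end = max(zs),
                            seed_slice = seed$z)
  }
  regions
}

#' Classify region voxels into air and involvement
#'
#' Region voxels with HU inside the closed air band become air; voxels
#' between the air band and the bone threshold become involvement (mucosal
#' thickening, cysts, fluid). Voxels at or above the bone threshold, or
#' below the air band, are intruding bone or artefact and are excluded
#' from both classes (and hence from the total volume).
#'
#' @param region one side's region from [propagate_sinus()].
#' @param volume the [ct_volume()] the region was segmented from.
#' @param params a [segmentation_params()] object.
#' @return List with `side`, `air` and `involvement`: pixel-index sets
#'   keyed by slice.
#' @export
classify_air_involvement <- function(region, volume,
                                     params = segmentation_params()) {
  stopifnot(!is.null(region))
  air <- list(); inv <- list()
  for (zc in names(region$slices)) {
    z <- as.integer(zc)
    idx <- region$slices[[zc]]
    hu <- volume$voxels[z, , ][idx]
    air[[zc]] <- idx[hu >= params$air_hu_low & hu <= params$air_hu_high]
    inv[[zc]] <- idx[hu > params$air_hu_high & hu < params$bone_threshold_hu]
  }
  list(side = region$side, air = air, involvement = inv)
}

#' Segment both maxillary sinuses in a CT volume
#'
#' Full pipeline: middle-slice-outward propagation of the watershed +
#' rule-based segmentation, followed by air/involvement banding, returning
#' a label map (1 right air, 2 right involvement, 3 left air, 4 left
#' involvement).
#'
#' @param volume a [ct_volume()].
#' @param params a [segmentation_params()] object.
#' @return An object of class `sinus_segmentation`: list with `label_map`
#'   (a [label_map()]), `regions`, `params`.
#' @export
segment_sinuses <- function(volume, params = segmentation_params()) {
  regions <- propagate_sinus(volume, params)
  d <- dim(volume$voxels)
  labels <- array(0L, dim = d)
  codes <- list(right = c(air = LABEL_RIGHT_AIR, inv = LABEL_RIGHT_INV),
                left = c(air = LABEL_LEFT_AIR, inv = LABEL_LEFT_INV))
  for (side in c("right", "left")) {
    region <- regions[[side]]
    if (is.null(region)) next
    cls <- classify_air_involvement(region, volume, params)
    for (zc in names(cls$air)) {
      z <- as.integer(zc)
      sl <- labels[z, , ]
      sl[cls$air[[zc]]] <- codes[[side]]["air"]
      sl[cls$involvement[[zc]]] <- codes[[side]]["inv"]
      labels[z, , ] <- sl
    }
  }
  structure(list(label_map = label_map(labels, volume$spacing_mm,
                                       volume$origin_mm),
                 regions = regions, params = params),
            class = "sinus_segmentation")
}

#' @export
print.sinus_segmentation <- function(x, ...) {
  cat("<sinus_segmentation>\n")
  for (side in c("right", "left")) {
    r <- x$regions[[side]]
    if (is.null(r)) cat("  ", side, ": not found\n", sep = "")
    else cat("  ", side, ": slices ", r$z_start, "-", r$z_end,
             " (seed ", r$seed_slice, ")\n", sep = "")
  }
  invisible(x)
}
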