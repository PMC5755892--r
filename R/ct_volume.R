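#' Calibrated CT volume
#'
#' Container for a Hounsfield-unit-calibrated CT volume. Voxels are stored
#' as a 3D array in `(slice, row, column)` order with slice index 1 the
#' most inferior slice when orientation metadata allows. All geometry is in
#' millimetres.
#'
#' @param voxels 3D numeric array of HU values, dimension order
#'   `(slice, row, column)`.
#' @param spacing_mm length-3 numeric: between-slice, row and column spacing
#'   in mm; all components must be positive.
#' @param origin_mm length-3 numeric, position of the first voxel in mm.
#' @param patient_orientation `"LPS-aligned"` when orientation metadata
#'   guarantees that increasing column index moves towards the patient's
#'   left (radiological convention), otherwise `"unknown"`.
#'
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0),
                      patient_orientation = c("LPS-aligned", "unknown")) {
  patient_orientation <- match.arg(patient_orientation)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (slice, row, column)", call. = FALSE)
  if (dim(voxels)[1] < 3L)
    stop("a CT volume needs at least 3 slices (a middle slice and neighbours)",
         call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers", call. = FALSE)
  rng <- range(voxels)
  if (rng[1] < -2048 || rng[2] > 4096) {
    warning("HU values outside [-2048, 4096] clamped", call. = FALSE)
    voxels[voxels < -2048] <- -2048
    voxels[voxels > 4096] <- 4096
  }
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm),
         patient_orientation = patient_orientation,
         slice_axis = 1L),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<ct_volume> ", d[1], " slices x ", d[2], " rows x ", d[3], " cols\n",
      sep = "")
  cat("  spacing (mm): ", paste(signif(x$spacing_mm, 4), collapse = " x "),
      "   orientation: ", x$patient_orientation, "\n", sep = "")
  cat("  HU range: [", round(min(x$voxels)), ", ", round(max(x$voxels)),
      "]\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

# label codes shared by the whole package
LABEL_RIGHT_AIR <- 1L
LABEL_RIGHT_INV <- 2L
LABEL_LEFT_AIR <- 3L
LABEL_LEFT_INV <- 4L

#' Sinus label map
#'
#' Integer voxel labels congruent with a [ct_volume()]: 0 background,
#' 1 right-sinus air, 2 right-sinus involvement, 3 left-sinus air,
#' 4 left-sinus involvement.
#'
#' @param labels 3D integer array, `(slice, row, column)` order.
#' @param spacing_mm length-3 numeric voxel spacing in mm.
#' @param origin_mm length-3 numeric origin in mm.
#'
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L | labels > 4L, na.rm = TRUE) || anyNA(labels))
    stop("label codes must lie in {0, 1, 2, 3, 4}", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers", call. = FALSE)
  structure(list(labels = labels, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cnt <- tabulate(x$labels + 1L, nbins = 5L)
  cat("<label_map> ", d[1], "x", d[2], "x", d[3], " voxels\n", sep = "")
  cat("  right: ", cnt[2], " air / ", cnt[3], " involvement;  left: ",
      cnt[4], " air / ", cnt[5], " involvement\n", sep = "")
  invisible(x)
}

#' @export
dim.label_map <- function(x) dim(x$labels)
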