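#' Read a CT volume from NIfTI
#'
#' Reads a 3D scalar NIfTI image already calibrated to Hounsfield units.
#' Axis order is normalised to the package convention
#' `(slice, row, column)`; NIfTI stores `(i = column, j = row, k = slice)`,
#' so the array is transposed on read and the header pixdim
#' `(dx, dy, dz)` becomes `spacing_mm = (dz, dy, dx)`.
#'
#' @param file_path path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
read_nifti <- function(file_path) {
  img <- RNifti::readNifti(file_path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D scalar image, got ", length(d), " dimensions",
         call. = FALSE)
  pd <- RNifti::pixdim(img)
  vox <- aperm(as.array(img), c(3L, 2L, 1L))
  orient <- tryCatch({
    xf <- RNifti::xform(img)
    rot <- xf[1:3, 1:3]
    # axis-aligned xform => in-plane axes map cleanly to patient axes
    if (all(abs(rot[upper.tri(rot)]) < 1e-6) &&
        all(abs(rot[lower.tri(rot)]) < 1e-6)) "LPS-aligned" else "unknown"
  }, error = function(e) "unknown")
  if (orient == "unknown")
    warning("orientation metadata absent or oblique; using image-column ",
            "convention for patient left/right", call. = FALSE)
  ct_volume(vox, spacing_mm = rev(pd[1:3]), patient_orientation = orient)
}

#' Write a CT volume to NIfTI
#'
#' @param volume a [ct_volume()].
#' @param file_path output path (`.nii` or `.nii.gz`).
#' @return `file_path`, invisibly.
#' @export
write_nifti_volume <- function(volume, file_path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(aperm(volume$voxels, c(3L, 2L, 1L)))
  RNifti::pixdim(img) <- rev(volume$spacing_mm)
  RNifti::writeNifti(img, file_path)
  invisible(file_path)
}

#' Write a label map to NIfTI
#'
#' Writes the integer label codes (0 background, 1 right air, 2 right
#' involvement, 3 left air, 4 left involvement) losslessly as an integer
#' NIfTI image.
#'
#' @param labels a [label_map()].
#' @param file_path output path.
#' @param reference optional [ct_volume()]; when given, the label grid must
#'   match its shape.
#' @return `file_path`, invisibly.
#' @export
write_label_map <- function(labels, file_path, reference = NULL) {
  stopifnot(inherits(labels, "label_map"))
  if (!is.null(reference) && !identical(dim(labels$labels),
                                        dim(reference$voxels)))
    stop("label map shape does not match the reference volume", call. = FALSE)
  img <- RNifti::asNifti(aperm(labels$labels, c(3L, 2L, 1L)))
  RNifti::pixdim(img) <- rev(labels$spacing_mm)
  RNifti::writeNifti(img, file_path, datatype = "int16")
  invisible(file_path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param file_path path to the NIfTI label image.
#' @return A [label_map()].
#' @export
read_label_map <- function(file_path) {
  img <- RNifti::readNifti(file_path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D label image", call. = FALSE)
  pd <- RNifti::pixdim(img)
  label_map(aperm(as.array(img), c(3L, 2L, 1L)), spacing_mm = rev(pd[1:3]))
}
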