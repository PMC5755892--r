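# Minimal DICOM support for single-frame CT series, explicit-VR little
# endian only. Covers exactly what a reconstructed paranasal CT export
# needs: geometry, rescale calibration and 16-bit pixel data. Multi-frame,
# compressed and implicit-VR files are rejected.

UID_TRANSFER_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_SOP_CLASS_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.9431"

# VRs whose explicit encoding uses a 4-byte length after 2 reserved bytes
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Modality rescale transform
#'
#' Converts stored pixel values to Hounsfield units,
#' `HU = slope * stored + intercept`.
#'
#' @param stored numeric vector of stored pixel values.
#' @param slope,intercept rescale slope and intercept from the DICOM header.
#' @return Numeric vector of HU values.
#' @export
dicom_rescale <- function(stored, slope, intercept) slope * stored + intercept

encode_element <- function(group, element, vr, value) {
  hdr <- writeBin(as.integer(c(group, element)), raw(), size = 2,
                  endian = "little")
  if (vr %in% c("US", "UL")) {
    body <- writeBin(as.integer(value), raw(),
                     size = if (vr == "US") 2L else 4L, endian = "little")
  } else if (vr %in% c("OW", "OB")) {
    body <- value # already raw
  } else {
    body <- charToRaw(as.character(value))
    if (length(body) %% 2L == 1L)
      body <- c(body, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  if (vr %in% LONG_VRS) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(body), raw(), size = 4, endian = "little"), body)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(length(body), raw(), size = 2, endian = "little"), body)
  }
}

dicom_ds <- function(x) paste(formatC(x, format = "fg", digits = 10),
                              collapse = "\\")

#' Write a CT volume as a DICOM series
#'
#' Writes one explicit-VR little-endian single-frame CT file per slice,
#' with signed 16-bit pixels, rescale slope 1 and intercept -1024 (HU are
#' therefore quantised to integers on write).
#'
#' @param volume a [ct_volume()].
#' @param directory_path output directory, created if needed.
#' @param series_uid optional series instance UID (a fresh one is derived
#'   from the volume dimensions by default so a series stays self-consistent).
#' @return The directory path, invisibly.
#' @export
write_dicom_series <- function(volume, directory_path,
                               series_uid = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  if (!dir.exists(directory_path))
    dir.create(directory_path, recursive = TRUE)
  intercept <- -1024
  if (is.null(series_uid))
    series_uid <- paste(UID_ROOT, d[1], d[2], d[3], "1", sep = ".")
  study_uid <- paste(UID_ROOT, d[1], d[2], d[3], "0", sep = ".")
  for (s in seq_len(d[1])) {
    sl <- volume$voxels[s, , ]
    # row-major pixel order: image rows one after another
    pix <- writeBin(as.integer(round(as.vector(t(sl)))) -
                      as.integer(intercept), raw(), size = 2,
                    endian = "little")
    sop_uid <- paste(series_uid, s, sep = ".")
    ipp <- c(volume$origin_mm[3], volume$origin_mm[2],
             volume$origin_mm[1] + (s - 1) * volume$spacing_mm[1])
    ds <- c(
      encode_element(0x0008, 0x0016, "UI", UID_SOP_CLASS_CT),
      encode_element(0x0008, 0x0018, "UI", sop_uid),
      encode_element(0x0008, 0x0060, "CS", "CT"),
      encode_element(0x0018, 0x0050, "DS", dicom_ds(volume$spacing_mm[1])),
      encode_element(0x0020, 0x000D, "UI", study_uid),
      encode_element(0x0020, 0x000E, "UI", series_uid),
      encode_element(0x0020, 0x0013, "IS", as.character(s)),
      encode_element(0x0020, 0x0032, "DS", dicom_ds(ipp)),
      encode_element(0x0020, 0x0037, "DS", dicom_ds(c(1, 0, 0, 0, 1, 0))),
      encode_element(0x0028, 0x0002, "US", 1L),
      encode_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      encode_element(0x0028, 0x0010, "US", d[2]),
      encode_element(0x0028, 0x0011, "US", d[3]),
      encode_element(0x0028, 0x0030, "DS",
                     dicom_ds(volume$spacing_mm[2:3])),
      encode_element(0x0028, 0x0100, "US", 16L),
      encode_element(0x0028, 0x0101, "US", 16L),
      encode_element(0x0028, 0x0102, "US", 15L),
      encode_element(0x0028, 0x0103, "US", 1L),
      encode_element(0x0028, 0x1052, "DS", dicom_ds(intercept)),
      encode_element(0x0028, 0x1053, "DS", "1"),
      encode_element(0x7FE0, 0x0010, "OW", pix))
    meta_body <- c(
      encode_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      encode_element(0x0002, 0x0002, "UI", UID_SOP_CLASS_CT),
      encode_element(0x0002, 0x0003, "UI", sop_uid),
      encode_element(0x0002, 0x0010, "UI", UID_TRANSFER_EXPLICIT_LE),
      encode_element(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".2")))
    meta <- c(encode_element(0x0002, 0x0000, "UL", length(meta_body)),
              meta_body)
    con <- file(file.path(directory_path,
                          sprintf("slice_%04d.dcm", s)), "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, ds), con)
    close(con)
  }
  invisible(directory_path)
}

parse_dicom_file <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) < 140 ||
      rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  pos <- 133L
  n <- length(bytes)
  tags <- list()
  u16 <- function(at) readBin(bytes[at:(at + 1L)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(bytes[at:(at + 3L)], "integer", size = 4,
                              endian = "little")
  in_meta <- TRUE
  transfer <- NULL
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (in_meta && group != 0x0002) {
      in_meta <- FALSE
      if (!identical(transfer, UID_TRANSFER_EXPLICIT_LE))
        stop("unsupported transfer syntax in ", path, call. = FALSE)
    }
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- u32(pos + 8L); body_at <- pos + 12L
    } else {
      len <- u16(pos + 6L); body_at <- pos + 8L
    }
    key <- sprintf("%04X,%04X", group, elem)
    if (len > 0L) {
      body <- bytes[body_at:(body_at + len - 1L)]
      val <- switch(vr,
        US = readBin(body, "integer", n = len / 2, size = 2,
                     endian = "little", signed = FALSE),
        UL = readBin(body, "integer", n = len / 4, size = 4,
                     endian = "little"),
        OW = body,
        OB = body,
        sub(" +$", "", rawToChar(body[body != as.raw(0)])))
    } else val <- NULL
    tags[[key]] <- val
    if (key == "0002,0010") transfer <- val
    pos <- body_at + len
  }
  tags
}

#' Read a DICOM series into a CT volume
#'
#' Reads all single-frame CT files in a directory, sorts them by spatial
#' position along the slice normal (not by filename), applies the modality
#' rescale transform and returns a calibrated [ct_volume()].
#'
#' @param directory_path directory containing one DICOM series.
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(directory_path) {
  files <- list.files(directory_path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 3L)
    stop("a series needs at least 3 slices, found ", length(files),
         call. = FALSE)
  slices <- lapply(files, parse_dicom_file)
  get1 <- function(tags, key, what) {
    v <- tags[[key]]
    if (is.null(v)) stop("missing ", what, " in series", call. = FALSE)
    v
  }
  modality <- vapply(slices, function(t) get1(t, "0008,0060", "modality"),
                     "")
  if (any(modality != "CT"))
    stop("non-CT modality in input (", paste(unique(modality),
         collapse = ", "), ")", call. = FALSE)
  series <- vapply(slices, function(t) get1(t, "0020,000E", "series UID"),
                   "")
  if (length(unique(series)) != 1L)
    stop("mixed series UIDs in directory", call. = FALSE)
  ds_num <- function(s) as.numeric(strsplit(s, "\\\\")[[1]])
  ipp <- t(vapply(slices,
                  function(t) ds_num(get1(t, "0020,0032",
                                          "image position (patient)")),
                  numeric(3)))
  iop <- ds_num(get1(slices[[1]], "0020,0037", "image orientation"))
  normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
              iop[3] * iop[4] - iop[1] * iop[6],
              iop[1] * iop[5] - iop[2] * iop[4])
  zpos <- as.vector(ipp %*% normal)
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]; ipp <- ipp[ord, , drop = FALSE]
  gaps <- diff(zpos)
  if (any(gaps <= 0))
    stop("duplicate or non-increasing slice positions", call. = FALSE)
  if ((max(gaps) - min(gaps)) / mean(gaps) >= 0.05)
    stop("inter-slice gap varies by >= 5%; inconsistent geometry",
         call. = FALSE)
  px <- lapply(slices, function(t) ds_num(get1(t, "0028,0030",
                                               "pixel spacing")))
  if (length(unique(vapply(px, paste, "", collapse = ","))) != 1L)
    stop("pixel spacing differs between slices", call. = FALSE)
  nrw <- get1(slices[[1]], "0028,0010", "rows")
  ncl <- get1(slices[[1]], "0028,0011", "columns")
  signed <- isTRUE(get1(slices[[1]], "0028,0103", "pixel representation") ==
                     1L)
  vox <- array(0, dim = c(length(slices), nrw, ncl))
  for (s in seq_along(slices)) {
    tg <- slices[[s]]
    slope <- as.numeric(tg[["0028,1053"]] %||% "1")
    inter <- as.numeric(tg[["0028,1052"]] %||% "0")
    body <- get1(tg, "7FE0,0010", "pixel data")
    stored <- readBin(body, "integer", n = nrw * ncl, size = 2,
                      endian = "little", signed = signed)
    vox[s, , ] <- matrix(dicom_rescale(stored, slope, inter),
                         nrow = nrw, byrow = TRUE)
  }
  orient <- if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) < 1e-4)
    "LPS-aligned" else "unknown"
  if (orient == "unknown")
    warning("oblique image orientation; using image-column convention ",
            "for patient left/right", call. = FALSE)
  ct_volume(vox, spacing_mm = c(mean(gaps), px[[1]][1], px[[1]][2]),
            origin_mm = c(zpos[1], ipp[1, 2], ipp[1, 1]),
            patient_orientation = orient)
}
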