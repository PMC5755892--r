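#' Per-sinus volumes from a label map
#'
#' Counts voxels per class per side and converts to physical volumes:
#' each volume is its voxel count times the voxel volume (product of the
#' three spacing components), reported in cm^3. Total = air + involvement
#' by construction.
#'
#' @param labels a [label_map()].
#' @return A tibble of class `sinus_measurements`, one row per side
#'   present, with columns `side`, `n_voxels_air`, `n_voxels_involvement`,
#'   `n_voxels_total`, `voxel_volume_mm3`, `air_volume_cm3`,
#'   `involvement_volume_cm3`, `total_volume_cm3`,
#'   `involvement_fraction`.
#' @export
compute_volumes <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  vv <- prod(labels$spacing_mm)
  cnt <- tabulate(labels$labels, nbins = 4L)
  per_side <- list(right = c(air = cnt[LABEL_RIGHT_AIR],
                             inv = cnt[LABEL_RIGHT_INV]),
                   left = c(air = cnt[LABEL_LEFT_AIR],
                            inv = cnt[LABEL_LEFT_INV]))
  rows <- list()
  for (side in c("right", "left")) {
    n_air <- unname(per_side[[side]]["air"])
    n_inv <- unname(per_side[[side]]["inv"])
    n_tot <- n_air + n_inv
    if (n_tot == 0L) {
      message("no voxels labelled for the ", side, " sinus; side omitted")
      next
    }
    rows[[side]] <- tibble::tibble(
      side = side,
      n_voxels_air = as.integer(n_air),
      n_voxels_involvement = as.integer(n_inv),
      n_voxels_total = as.integer(n_tot),
      voxel_volume_mm3 = vv,
      air_volume_cm3 = n_air * vv / 1000,
      involvement_volume_cm3 = n_inv * vv / 1000,
      total_volume_cm3 = n_tot * vv / 1000,
      involvement_fraction = as.numeric(n_inv) / as.numeric(n_tot))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sinus_measurements", class(out))
  out
}

label_class_mask <- function(labels, class = c("total", "air",
                                               "involvement"),
                             side = c("both", "right", "left")) {
  class <- match.arg(class)
  side <- match.arg(side)
  codes <- switch(class,
                  total = c(LABEL_RIGHT_AIR, LABEL_RIGHT_INV,
                            LABEL_LEFT_AIR, LABEL_LEFT_INV),
                  air = c(LABEL_RIGHT_AIR, LABEL_LEFT_AIR),
                  involvement = c(LABEL_RIGHT_INV, LABEL_LEFT_INV))
  if (side == "right") codes <- codes[codes <= 2L]
  if (side == "left") codes <- codes[codes >= 3L]
  array(labels$labels %in% codes, dim = dim(labels$labels))
}

#' Extract a triangulated surface of a label class
#'
#' Builds the closed boundary surface of the selected voxel class as a
#' watertight triangle mesh in mm coordinates. Faces are the exact voxel
#' boundary (every boundary voxel face becomes two triangles, outward
#' oriented), so the divergence-theorem volume of the mesh equals the
#' voxel count times the voxel volume exactly. An optional Laplacian
#' smoothing pass is available for display; measurements never come from
#' the mesh.
#'
#' @param labels a [label_map()].
#' @param class `"total"`, `"air"` or `"involvement"`.
#' @param side `"both"`, `"right"` or `"left"`.
#' @param smooth_iterations Laplacian smoothing passes (display only).
#' @return A list of class `sinus_mesh` with `vertices` (n x 3 matrix,
#'   mm, columns x/y/z = column/row/slice direction) and `faces`
#'   (m x 3 integer matrix, 1-based, outward orientation).
#' @export
extract_surface <- function(labels, class = "total", side = "both",
                            smooth_iterations = 0L) {
  stopifnot(inherits(labels, "label_map"))
  mask <- label_class_mask(labels, class, side)
  if (!any(mask)) stop("selected class is empty", call. = FALSE)
  d <- dim(mask)
  sp <- labels$spacing_mm
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  idx <- which(pad)
  dp <- dim(pad)
  arr_ind <- arrayInd(idx, dp)
  quads <- list()
  shift_idx <- function(ds, dr, dc) {
    idx + ds + dr * dp[1] + dc * dp[1] * dp[2]
  }
  # six face directions: (axis, sign) pairs in (slice, row, col)
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  # voxel corner offsets for the face normal to each direction, ordered so
  # the right-hand rule gives an outward normal
  face_corners <- function(dir) {
    ax <- which(dir != 0)
    s <- dir[ax]
    others <- setdiff(1:3, ax)
    # keep (ax, others) an even permutation so cross(e_o1, e_o2) = +e_ax
    if (ax == 2L) others <- rev(others)
    base <- matrix(0, 4, 3)
    base[, ax] <- (s + 1) / 2
    base[2, others[1]] <- 1
    base[3, others] <- 1
    base[4, others[2]] <- 1
    # grid axes are (slice, row, col) but vertices are emitted as
    # (x=col, y=row, z=slice): an odd permutation, so flip the winding
    if (s > 0) base[c(1, 4, 3, 2), ] else base
  }
  for (dir in dirs) {
    nb <- shift_idx(dir[1], dir[2], dir[3])
    face_here <- !pad[nb]
    if (!any(face_here)) next
    cells <- arr_ind[face_here, , drop = FALSE] - 1L # unpad, 0-based corner
    fc <- face_corners(dir)
    corner_ids <- matrix(0L, nrow(cells), 4L)
    for (j in 1:4) {
      cz <- cells[, 1] - 1L + fc[j, 1]
      cr <- cells[, 2] - 1L + fc[j, 2]
      cc <- cells[, 3] - 1L + fc[j, 3]
      k <- cz + (d[1] + 1L) * (cr + (d[2] + 1L) * cc)
      corner_ids[, j] <- k
    }
    quads[[length(quads) + 1L]] <- corner_ids
  }
  corner_all <- do.call(rbind, quads)
  uk <- sort(unique(as.vector(corner_all)))
  lookup <- match(as.vector(corner_all), uk)
  corner_idx <- matrix(lookup, nrow(corner_all), 4L)
  # decode corner keys back to grid coordinates -> mm
  cz <- uk %% (d[1] + 1L)
  rest <- uk %/% (d[1] + 1L)
  cr <- rest %% (d[2] + 1L)
  cc <- rest %/% (d[2] + 1L)
  vertices <- cbind(x = cc * sp[3], y = cr * sp[2], z = cz * sp[1])
  faces <- rbind(corner_idx[, c(1, 2, 3)], corner_idx[, c(1, 3, 4)])
  if (smooth_iterations > 0L)
    vertices <- laplacian_smooth(vertices, faces, smooth_iterations)
  structure(list(vertices = vertices, faces = faces,
                 class = class, side = side),
            class = "sinus_mesh")
}

# display-only umbrella smoothing: each vertex moves halfway towards the
# mean of its edge neighbours
laplacian_smooth <- function(vertices, faces, iterations) {
  edges <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  n <- nrow(vertices)
  for (it in seq_len(iterations)) {
    nb_sum <- matrix(0, n, 3)
    nb_cnt <- numeric(n)
    for (k in 1:2) {
      from <- edges[, k]; to <- edges[, 3 - k]
      for (j in 1:3)
        nb_sum[, j] <- nb_sum[, j] + tapply_sum(vertices[to, j], from, n)
      nb_cnt <- nb_cnt + tabulate(from, nbins = n)
    }
    vertices <- 0.5 * vertices + 0.5 * nb_sum / pmax(nb_cnt, 1)
  }
  vertices
}

tapply_sum <- function(x, by, n) {
  out <- numeric(n)
  agg <- rowsum(x, by)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Signed volume of a closed triangle mesh
#'
#' Divergence-theorem volume; positive for outward-oriented closed
#' surfaces.
#'
#' @param mesh a `sinus_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
                 b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
                 b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(rowSums(a * cross)) / 6
}

#' Check mesh watertightness
#'
#' A closed surface has every undirected edge shared by exactly two
#' triangles.
#'
#' @param mesh a `sinus_mesh`.
#' @return `TRUE` or `FALSE`.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' @export
print.sinus_mesh <- function(x, ...) {
  cat("<sinus_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " triangles (", x$class, ", ", x$side, ")\n", sep = "")
  invisible(x)
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh a `sinus_mesh`.
#' @param file_path output `.ply` path.
#' @return `file_path`, invisibly.
#' @export
write_ply <- function(mesh, file_path) {
  con <- file(file_path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"),
             con)
  writeLines(apply(format(mesh$vertices, trim = TRUE), 1, paste,
                   collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(file_path)
}

#' Write a mesh as ASCII STL
#'
#' @param mesh a `sinus_mesh`.
#' @param file_path output `.stl` path.
#' @return `file_path`, invisibly.
#' @export
write_stl <- function(mesh, file_path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(file_path, "w")
  on.exit(close(con))
  writeLines("solid sinus", con)
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  txt <- paste0("facet normal ", nrm[, 1], " ", nrm[, 2], " ", nrm[, 3],
                "\n outer loop\n  vertex ",
                a[, 1], " ", a[, 2], " ", a[, 3], "\n  vertex ",
                b[, 1], " ", b[, 2], " ", b[, 3], "\n  vertex ",
                cc[, 1], " ", cc[, 2], " ", cc[, 3],
                "\n endloop\nendfacet")
  writeLines(txt, con)
  writeLines("endsolid sinus", con)
  invisible(file_path)
}

#' Write a measurement report as JSON
#'
#' @param measurements a `sinus_measurements` tibble from
#'   [compute_volumes()].
#' @param file_path output `.json` path.
#' @param exam_id identifier embedded in the report.
#' @param params optional [segmentation_params()] echoed into the report.
#' @return `file_path`, invisibly.
#' @export
write_measurement_report <- function(measurements, file_path,
                                     exam_id = "exam", params = NULL) {
  per_side <- lapply(split(measurements, measurements$side), function(m) {
    list(total_cm3 = round(m$total_volume_cm3, 2),
         air_cm3 = round(m$air_volume_cm3, 2),
         involvement_cm3 = round(m$involvement_volume_cm3, 2),
         involvement_fraction = m$involvement_fraction,
         n_voxels_total = m$n_voxels_total,
         n_voxels_air = m$n_voxels_air,
         n_voxels_involvement = m$n_voxels_involvement,
         voxel_volume_mm3 = m$voxel_volume_mm3)
  })
  report <- list(exam_id = exam_id, sides = per_side,
                 parameters = unclass_params(params),
                 tool = paste0("sinusvol ",
                               as.character(utils::packageVersion("sinusvol"))))
  jsonlite::write_json(report, file_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file_path)
}

unclass_params <- function(params) {
  if (is.null(params)) return(NULL)
  p <- unclass(params)
  p$rule_params <- unclass(p$rule_params)
  p
}
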