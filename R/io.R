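# File formats: image sequences and displacement fields as NIfTI (RNifti),
# surfaces as ASCII STL, meshes and fields as legacy ASCII VTK, planar
# records and waveforms as CSV, reports as JSON.

#' Write an image sequence as per-phase NIfTI volumes
#'
#' @param seq_ an \linkS4class{ImageSequence}
#' @param dir output directory (created if missing)
#' @param prefix file name prefix
#' @return invisibly, the written file paths
#' @export
writeImageSequence <- function(seq_, dir, prefix = "phase") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v1 <- getVolume(seq_, 1L)
  paths <- vapply(seq_len(nPhases(seq_)), function(i) {
    v <- getVolume(seq_, i)
    arr <- v@data
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    img <- RNifti::asNifti(arr, pixdim = c(v@spacing, 1)[1:3])
    path <- file.path(dir, sprintf("%s_%02d.nii.gz", prefix, i - 1L))
    RNifti::writeNifti(img, path)
    path
  }, "")
  meta <- list(nPhases = nPhases(seq_), period = seq_@period,
               spacing = v1@spacing, origin = v1@origin,
               times = vapply(seq_@volumes, function(v) v@time, 0))
  jsonlite::write_json(meta, file.path(dir, sprintf("%s_index.json", prefix)),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read an image sequence written by \code{\link{writeImageSequence}}
#'
#' @param dir directory containing the per-phase NIfTI files and index
#' @param prefix file name prefix
#' @return an \linkS4class{ImageSequence}
#' @export
readImageSequence <- function(dir, prefix = "phase") {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_index.json", prefix)),
                              simplifyVector = TRUE)
  vols <- lapply(seq_len(meta$nPhases), function(i) {
    img <- RNifti::readNifti(file.path(dir, sprintf("%s_%02d.nii.gz",
                                                    prefix, i - 1L)))
    arr <- array(as.vector(img), dim(img))
    if (length(meta$spacing) == 2L && length(dim(arr)) == 3L)
      arr <- arr[, , 1]
    imageVolume(arr, meta$spacing, meta$origin, phase = i - 1L,
                time = meta$times[i])
  })
  new("ImageSequence", volumes = vols, period = meta$period)
}

#' Write a displacement field as per-instance multi-component NIfTI
#'
#' Each instance is written as one NIfTI file with the vector component as
#' the last dimension, plus a JSON index (time stamps, grid, count).
#'
#' @param f a \linkS4class{DisplacementField}
#' @param dir output directory
#' @param prefix file name prefix
#' @export
writeDisplacementField <- function(f, dir, prefix = "disp") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(f@d)) {
    arr <- f@d[[i]]
    RNifti::writeNifti(RNifti::asNifti(arr),
                       file.path(dir, sprintf("%s_%02d.nii.gz", prefix, i - 1L)))
  }
  jsonlite::write_json(
    list(nInstances = length(f@d), times = f@times, spacing = f@spacing,
         origin = f@origin),
    file.path(dir, sprintf("%s_index.json", prefix)),
    auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Read a displacement field written by \code{\link{writeDisplacementField}}
#' @param dir directory
#' @param prefix file name prefix
#' @return a \linkS4class{DisplacementField}
#' @export
readDisplacementField <- function(dir, prefix = "disp") {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_index.json", prefix)),
                              simplifyVector = TRUE)
  d <- lapply(seq_len(meta$nInstances), function(i) {
    img <- RNifti::readNifti(file.path(dir, sprintf("%s_%02d.nii.gz",
                                                    prefix, i - 1L)))
    array(as.vector(img), dim(img))
  })
  new("DisplacementField", d = d, times = meta$times,
      spacing = meta$spacing, origin = meta$origin)
}

#' Write a triangulated surface as ASCII STL
#'
#' @param nodes n x 3 vertex coordinates [mm]
#' @param triangles m x 3 connectivity
#' @param path output file
#' @param name solid name
#' @export
writeSTL <- function(nodes, triangles, path, name = "surface") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(triangles))) {
    p <- nodes[triangles[i, ], , drop = FALSE]
    nrm <- c((p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) -
               (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
             (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) -
               (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
             (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
               (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeLines(c(sprintf("  facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", p[, 1], p[, 2], p[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Write a simplex mesh (with optional point data) as legacy ASCII VTK
#'
#' @param mesh a \linkS4class{SimplexMesh}
#' @param path output .vtk file
#' @param nodes optional deformed positions
#' @param pointData named list of per-node scalar vectors or n x d matrices
#' @export
writeVTK <- function(mesh, path, nodes = mesh@nodes, pointData = list()) {
  d <- ncol(nodes)
  n3 <- cbind(nodes, matrix(0, nrow(nodes), 3 - d))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(n3))), con)
  write(t(n3), con, ncolumns = 3)
  nel <- nrow(mesh@elements); nv <- ncol(mesh@elements)
  writeLines(sprintf("CELLS %d %d", nel, nel * (nv + 1L)), con)
  write(t(cbind(nv, mesh@elements - 1L)), con, ncolumns = nv + 1L)
  writeLines(sprintf("CELL_TYPES %d", nel), con)
  write(rep(if (nv == 3L) 5L else 10L, nel), con, ncolumns = 1)
  if (length(pointData)) {
    writeLines(sprintf("POINT_DATA %d", nrow(n3)), con)
    for (nm in names(pointData)) {
      val <- pointData[[nm]]
      if (is.matrix(val)) {
        v3 <- cbind(val, matrix(0, nrow(val), 3 - ncol(val)))
        writeLines(sprintf("VECTORS %s double", nm), con)
        write(t(v3), con, ncolumns = 3)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        write(val, con, ncolumns = 1)
      }
    }
  }
  invisible(path)
}

#' Write a planar record as CSV
#'
#' Long format with columns plane_id, t, x, z, u_inplane, w_inplane, g
#' (and v_out when stored).
#'
#' @param record a \linkS4class{PlanarRecord}
#' @param path output .csv file
#' @export
writePlanarRecordCSV <- function(record, path) {
  grid <- expand.grid(x = record@x, z = record@z, t = record@times)
  df <- data.frame(plane_id = record@planeId, t = grid$t, x = grid$x,
                   z = grid$z,
                   u_inplane = as.vector(record@u),
                   w_inplane = as.vector(record@w),
                   g = as.vector(record@g))
  if (!is.null(record@v)) df$v_out <- as.vector(record@v)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a planar record CSV written by \code{\link{writePlanarRecordCSV}}
#' @param path .csv file
#' @return a \linkS4class{PlanarRecord}
#' @export
readPlanarRecordCSV <- function(path) {
  df <- read.csv(path)
  xs <- sort(unique(df$x)); zs <- sort(unique(df$z))
  tms <- sort(unique(df$t))
  dimR <- c(length(xs), length(zs), length(tms))
  ord <- order(match(df$t, tms), match(df$z, zs), match(df$x, xs))
  shape <- function(v) array(v[ord], dimR)
  new("PlanarRecord", x = xs, z = zs, times = tms,
      u = shape(df$u_inplane), w = shape(df$w_inplane),
      v = if ("v_out" %in% names(df)) shape(df$v_out) else NULL,
      g = shape(df$g), planeId = as.integer(df$plane_id[1]),
      pose = list())
}

#' Write an inlet waveform as CSV plus JSON metadata
#'
#' @param wf an \linkS4class{InletWaveform}
#' @param csvPath output .csv (t, Q_m3s, Q_Lmin, U_inlet)
#' @param jsonPath output .json metadata (D, area, ratio, offset)
#' @export
writeInletWaveform <- function(wf, csvPath, jsonPath = NULL) {
  write.csv(data.frame(t = wf@times, Q_m3s = wf@Q, Q_Lmin = wf@Q * 60000,
                       U_inlet = wf@U), csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(D_mm = wf@D, area_m2 = wf@area,
                              correction_ratio = wf@ratio,
                              offset_ms = wf@offset),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}
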