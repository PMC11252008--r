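## Reading and writing volumes, label maps, meshes and result tables.
## TIFF goes through the in-package baseline codec (page order = z,
## ImageJ-style resolution metadata); HDF5 through rhdf5 with a voxel_nm
## attribute on each dataset. Voxel indices are 0-based on disk interfaces;
## bounding boxes are half-open [lo, hi).

.io_format <- function(path, format = c("auto", "tiff", "hdf5")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("h5", "hdf5", "he5")) return("hdf5")
  stop("cannot infer format from extension: ", path)
}

#' Read a 3D volume from TIFF or HDF5
#'
#' Restores the voxel array and its physical spacing. Files without spacing
#' metadata fall back to 50 nm isotropic voxels with a warning.
#'
#' @param path File path.
#' @param format "auto" (by extension), "tiff" or "hdf5".
#' @param dataset HDF5 dataset name (default "volume").
#' @param name Channel name for the returned object.
#' @return A [Volume-class].
#' @export
readVolume <- function(path, format = "auto", dataset = "volume",
                       name = "volume") {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- .io_format(path, format)
  if (format == "tiff") {
    r <- .tiff_read(path)
    if (length(dim(r$data)) != 3L) stop("not a 3D volume: ", path)
    return(Volume(r$data, voxelNm = r$voxelNm, name = name))
  }
  data <- rhdf5::h5read(path, dataset)
  if (length(dim(data)) != 3L) stop("not a 3D dataset: ", dataset)
  att <- rhdf5::h5readAttributes(path, dataset)
  vox <- att[["voxel_nm"]]
  if (is.null(vox)) {
    warning("HDF5 dataset lacks a voxel_nm attribute; assuming 50 nm")
    vox <- c(50, 50, 50)
  }
  Volume(array(as.numeric(data), dim(data)), voxelNm = as.numeric(vox),
         name = name)
}

#' Write a 3D volume to TIFF or HDF5
#'
#' Integer data round-trip losslessly in both formats; floating data are
#' stored at full (64-bit) precision in HDF5 and 32-bit in TIFF.
#'
#' @param volume A [Volume-class] or [LabelMap-class].
#' @param path Destination path.
#' @param format "auto", "tiff" or "hdf5".
#' @param dataset HDF5 dataset name.
#' @return The path, invisibly.
#' @export
writeVolume <- function(volume, path, format = "auto", dataset = "volume") {
  stopifnot(is(volume, "VoxelGrid"))
  format <- .io_format(path, format)
  if (format == "tiff") {
    .tiff_write(volume@data, path, voxelNm = volume@voxelNm)
    return(invisible(path))
  }
  if (file.exists(path)) {
    fid <- rhdf5::H5Fopen(path)
    if (rhdf5::H5Lexists(fid, dataset)) rhdf5::h5delete(fid, dataset)
    rhdf5::H5Fclose(fid)
  } else rhdf5::h5createFile(path)
  ## intermediate groups must exist before writing a nested dataset
  parts <- strsplit(dataset, "/", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) > 1L) {
    fid <- rhdf5::H5Fopen(path)
    for (i in seq_len(length(parts) - 1L)) {
      grp <- paste(parts[seq_len(i)], collapse = "/")
      if (!rhdf5::H5Lexists(fid, grp)) rhdf5::h5createGroup(fid, grp)
    }
    rhdf5::H5Fclose(fid)
  }
  rhdf5::h5write(volume@data, path, dataset)
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, dataset)
  rhdf5::h5writeAttribute(volume@voxelNm, did, "voxel_nm")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read an instance label map
#'
#' @inheritParams readVolume
#' @return A [LabelMap-class].
#' @export
readLabelMap <- function(path, format = "auto", dataset = "labels") {
  v <- readVolume(path, format, dataset)
  d <- v@data
  if (any(d < 0) || any(d != round(d)))
    stop("not a label map: negative or non-integer values")
  LabelMap(array(as.integer(round(d)), dim(d)), voxelNm = v@voxelNm)
}

#' Write an instance label map
#'
#' @param labels A [LabelMap-class] (or [BinaryMask-class], stored as 0/1).
#' @inheritParams writeVolume
#' @export
writeLabelMap <- function(labels, path, format = "auto", dataset = "labels") {
  if (is(labels, "BinaryMask"))
    labels <- LabelMap(array(as.integer(labels@data), dim(labels@data)),
                       voxelNm = labels@voxelNm)
  writeVolume(labels, path, format, dataset)
}

#' Write a triangle mesh as OBJ or PLY (ASCII)
#'
#' Vertex and face counts are preserved on re-read; units are micrometres.
#'
#' @param mesh A [TriMesh-class]; writing an empty mesh is an error.
#' @param path Destination path.
#' @param format "auto" (by extension), "obj" or "ply".
#' @return The path, invisibly.
#' @export
writeMesh <- function(mesh, path, format = c("auto", "obj", "ply")) {
  stopifnot(is(mesh, "TriMesh"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("obj", "ply")) stop("cannot infer mesh format: ", path)
    format <- ext
  }
  v <- mesh@vertices; f <- mesh@faces
  if (!nrow(v) || !nrow(f)) stop("refusing to write an empty mesh")
  if (format == "obj") {
    lines <- c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  } else {
    lines <- c("ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(v)),
      "property float z", "property float y", "property float x",
      sprintf("element face %d", nrow(f)),
      "property list uchar int vertex_indices", "end_header",
      sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
      sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an OBJ or PLY triangle mesh
#'
#' @param path File path.
#' @param format "auto", "obj" or "ply".
#' @return A [TriMesh-class].
#' @export
readMesh <- function(path, format = c("auto", "obj", "ply")) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (format == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(s)
      as.numeric(s[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(s)
      as.integer(sub("/.*", "", s[2:4]))))
    return(TriMesh(v, f))
  }
  if (format != "ply") stop("unsupported mesh format: ", format)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  body <- which(lines == "end_header") + 1L
  v <- do.call(rbind, lapply(strsplit(lines[body:(body + nv - 1L)], "\\s+"),
                             function(s) as.numeric(s[1:3])))
  f <- do.call(rbind, lapply(
    strsplit(lines[(body + nv):(body + nv + nf - 1L)], "\\s+"),
    function(s) as.integer(s[2:4]) + 1L))
  TriMesh(v, f)
}

#' Write result records as CSV
#'
#' One row per bouton, cleft or edge; a header line is always present.
#'
#' @param records A data.frame.
#' @param path Destination .csv path.
#' @return The path, invisibly.
#' @export
writeTables <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read back a result table
#' @param path A .csv path written by [writeTables()].
#' @return A data.frame.
#' @export
readTables <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write metric curves or graphs as JSON
#'
#' @param x A list or data.frame (e.g. a precision-recall curve).
#' @param path Destination .json path.
#' @return The path, invisibly.
#' @export
writeMetricsJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
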