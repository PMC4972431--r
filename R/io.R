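# File formats: MRtrix .tck tractograms (binary Float32LE), NIfTI
# volumes (via RNifti), GIfTI and legacy-VTK ASCII surface meshes,
# mcflirt-style motion parameter text, 4x4 affine text, and JSON
# configuration.  Writers are byte-stable under fixed input.

#' Write a tractogram to an MRtrix .tck file
#'
#' Binary format: "mrtrix tracks" magic, ASCII key/value header with
#' \code{datatype: Float32LE} and an END keyword, then little-endian
#' float32 point triplets with a NaN triplet after each track and an Inf
#' triplet terminating the stream.
#'
#' @param t a [Tractogram-class].
#' @param path output file path.
#' @export
writeTck <- function(t, path) {
  n <- nTracks(t)
  body <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", n,
                 "\nfile: . ")
  # the offset includes its own digits; stabilise by iteration
  offset <- nchar(body) + 10L
  for (i in 1:3) offset <- nchar(body) + nchar(as.character(offset)) + 5L
  header <- paste0(body, offset, "\nEND\n")
  stopifnot(nchar(header) == offset)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  for (i in seq_len(n)) {
    writeBin(as.vector(t(t@streamlines[[i]])), con, size = 4,
             endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRtrix .tck file
#'
#' @param path input file path.
#' @return a [Tractogram-class]; header key/values in the provenance.
#' @export
readTck <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (!length(raw) || rawToChar(raw[1:13]) != "mrtrix tracks")
    stop("bad magic: not an MRtrix track file")
  # header is ASCII up to the END line; locate it
  txtEnd <- NULL
  nl <- which(raw == as.raw(10L))
  prev <- 1L
  header <- character(0)
  for (pos in nl) {
    line <- rawToChar(raw[prev:(pos - 1L)])
    header <- c(header, line)
    prev <- pos + 1L
    if (line == "END") { txtEnd <- pos; break }
    if (pos > 65536L) break
  }
  if (is.null(txtEnd)) stop("truncated header: END keyword not found")
  kv <- header[grepl(":", header, fixed = TRUE)]
  keys <- sub(":.*", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  names(vals) <- keys
  if (!identical(unname(vals["datatype"]), "Float32LE"))
    stop("unsupported datatype: ", vals["datatype"])
  offset <- as.integer(sub(".*\\s", "", vals["file"]))
  nFloats <- (length(raw) - offset) %/% 4L
  if (nFloats %% 3L != 0L)
    stop("truncated stream at byte offset ", offset + 4L * nFloats)
  xyz <- matrix(readBin(raw[(offset + 1L):length(raw)], "numeric",
                        n = nFloats, size = 4, endian = "little"),
                ncol = 3, byrow = TRUE)
  sep <- which(!is.finite(xyz[, 1]))
  streamlines <- list()
  start <- 1L
  for (sp in sep) {
    if (sp > start)
      streamlines[[length(streamlines) + 1L]] <-
        xyz[start:(sp - 1L), , drop = FALSE]
    start <- sp + 1L
    if (is.infinite(xyz[sp, 1])) break
  }
  Tractogram(streamlines, provenance = list(header = as.list(vals)))
}

# ---- NIfTI -----------------------------------------------------------------

#' Read a NIfTI volume
#' @param path .nii or .nii.gz file.
#' @return list with \code{data} (array) and \code{affine} (4x4,
#'   voxel-to-world, 0-based indices).
#' @export
readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = dim(aff))
  dat <- as.array(img)
  dat <- array(as.vector(dat), dim(dat))  # plain array, no image class
  list(data = dat, affine = aff)
}

#' Write a NIfTI volume
#' @param data 3D or 4D array.
#' @param affine 4x4 voxel-to-world transform.
#' @param path output path (.nii or .nii.gz).
#' @export
writeNiftiVolume <- function(data, affine, path) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- GIfTI surfaces --------------------------------------------------------

#' Write a surface mesh as GIfTI (ASCII encoding)
#' @param mesh a [SurfaceMesh-class].
#' @param path output .gii path.
#' @export
writeGifti <- function(mesh, path) {
  fmtRow <- function(m) paste(apply(m, 1, paste, collapse = " "),
                              collapse = "\n")
  v <- mesh@vertices
  tr <- mesh@triangles - 1L   # GIfTI indices are 0-based
  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<GIFTI Version=\"1.0\" NumberOfDataArrays=\"2\">\n",
    "<DataArray Intent=\"NIFTI_INTENT_POINTSET\" DataType=\"NIFTI_TYPE_FLOAT32\"",
    " ArrayIndexingOrder=\"RowMajorOrder\" Dimensionality=\"2\" Dim0=\"",
    nrow(v), "\" Dim1=\"3\" Encoding=\"ASCII\" Endian=\"LittleEndian\">\n",
    "<Data>", fmtRow(signif(v, 9)), "</Data>\n</DataArray>\n",
    "<DataArray Intent=\"NIFTI_INTENT_TRIANGLE\" DataType=\"NIFTI_TYPE_INT32\"",
    " ArrayIndexingOrder=\"RowMajorOrder\" Dimensionality=\"2\" Dim0=\"",
    nrow(tr), "\" Dim1=\"3\" Encoding=\"ASCII\" Endian=\"LittleEndian\">\n",
    "<Data>", fmtRow(tr), "</Data>\n</DataArray>\n</GIFTI>\n")
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Read a GIfTI surface mesh
#'
#' Supports ASCII, Base64Binary and GZipBase64Binary encodings of
#' float32/int32 data arrays.
#'
#' @param path .gii file.
#' @return a [SurfaceMesh-class].
#' @export
readGifti <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  verts <- tris <- NULL
  for (a in arrays) {
    intent <- xml2::xml_attr(a, "Intent")
    enc <- xml2::xml_attr(a, "Encoding")
    dtype <- xml2::xml_attr(a, "DataType")
    n0 <- as.integer(xml2::xml_attr(a, "Dim0"))
    txt <- xml2::xml_text(xml2::xml_find_first(a, ".//Data"))
    vals <- if (enc == "ASCII") {
      scan(text = txt, quiet = TRUE)
    } else {
      bin <- jsonlite::base64_dec(gsub("\\s", "", txt))
      if (enc == "GZipBase64Binary") bin <- memDecompress(bin, "gzip")
      if (dtype == "NIFTI_TYPE_INT32")
        readBin(bin, "integer", n = length(bin) / 4L, size = 4,
                endian = "little")
      else
        readBin(bin, "numeric", n = length(bin) / 4L, size = 4,
                endian = "little")
    }
    m <- matrix(vals, nrow = n0, ncol = 3, byrow = TRUE)
    if (intent == "NIFTI_INTENT_POINTSET") verts <- m
    if (intent == "NIFTI_INTENT_TRIANGLE") tris <- m + 1L
  }
  if (is.null(verts) || is.null(tris))
    stop("GIfTI file lacks pointset or triangle array")
  SurfaceMesh(verts, tris)
}

# ---- legacy VTK polydata ---------------------------------------------------

#' Write a mesh as legacy ASCII VTK polydata
#' @param mesh a [SurfaceMesh-class].
#' @param path output .vtk path.
#' @export
writeVtkPolydata <- function(mesh, path) {
  v <- mesh@vertices; tr <- mesh@triangles - 1L
  lines <- c("# vtk DataFile Version 3.0", "surface", "ASCII",
             "DATASET POLYDATA",
             paste("POINTS", nrow(v), "float"),
             apply(signif(v, 9), 1, paste, collapse = " "),
             paste("POLYGONS", nrow(tr), 4L * nrow(tr)),
             apply(tr, 1, function(r) paste(c(3L, r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a legacy ASCII VTK polydata mesh
#' @param path .vtk file.
#' @return a [SurfaceMesh-class].
#' @export
readVtkPolydata <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  vals <- scan(text = paste(lines[(ip + 1):length(lines)], collapse = "\n"),
               n = 3L * np, quiet = TRUE)
  verts <- matrix(vals, ncol = 3, byrow = TRUE)
  it <- grep("^POLYGONS", lines)[1]
  nt <- as.integer(strsplit(lines[it], "\\s+")[[1]][2])
  tvals <- scan(text = paste(lines[(it + 1):length(lines)], collapse = "\n"),
                n = 4L * nt, quiet = TRUE)
  tm <- matrix(tvals, ncol = 4, byrow = TRUE)
  if (any(tm[, 1] != 3L)) stop("non-triangular polygons are not supported")
  SurfaceMesh(verts, tm[, 2:4] + 1L)
}

# ---- motion parameters and transforms --------------------------------------

#' Read a six-column motion parameter file
#'
#' mcflirt \code{.par} dialect: whitespace-separated, three rotations
#' (radians) then three translations (mm) per frame by default.
#'
#' @param path text file.
#' @param order "rot-first" (mcflirt, default) or "trans-first".
#' @param TR repetition time used for frame times (default 3).
#' @return a [MotionTrace-class].
#' @export
readMotionPar <- function(path, order = c("rot-first", "trans-first"),
                          TR = 3) {
  order <- match.arg(order)
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (ncol(m) != 6L) stop("expected six columns")
  if (order == "rot-first")
    MotionTrace(m[, 4:6, drop = FALSE], m[, 1:3, drop = FALSE], TR = TR)
  else
    MotionTrace(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE], TR = TR)
}

#' Write a motion trace in mcflirt .par layout (rotations first)
#' @param m a [MotionTrace-class].
#' @param path output path.
#' @export
writeMotionPar <- function(m, path) {
  utils::write.table(cbind(m@rotations, m@translations), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 4x4 affine from whitespace text
#' @param path text file with four rows of four numbers.
#' @export
readAffineText <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (!all(dim(m) == c(4L, 4L))) stop("expected a 4x4 matrix")
  dimnames(m) <- NULL
  m
}

# ---- planar ROIs (JSON) ----------------------------------------------------

#' Write a set of planar ROIs to JSON
#' @param rois named list of [PlanarROI-class] objects.
#' @param path output .json path.
#' @export
writePlanarROIs <- function(rois, path) {
  obj <- lapply(rois, function(r) list(
    affine = r@affine, dim = r@dim, axis = r@axis,
    sliceIndex = r@sliceIndex, voxels = r@voxels, role = r@role))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read planar ROIs from JSON
#' @param path .json file produced by [writePlanarROIs()].
#' @return named list of [PlanarROI-class] objects.
#' @export
readPlanarROIs <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(r) PlanarROI(
    affine = as.matrix(r$affine), dim = r$dim, axis = r$axis,
    sliceIndex = r$sliceIndex, voxels = as.matrix(r$voxels),
    role = r$role))
}
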