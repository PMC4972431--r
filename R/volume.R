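#' Construct a LabelVolume
#'
#' @param voxels 3D integer array of labels.
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices).
#' @param labels named integer vector mapping roles ("WM", "GM", "CSF",
#'   "background") to label values.
#' @return a [LabelVolume-class].
#' @export
LabelVolume <- function(voxels, affine = diag(4),
                        labels = c(background = 0L, GM = 1L, WM = 2L,
                                   CSF = 3L)) {
  storage.mode(voxels) <- "integer"
  new("LabelVolume", voxels = voxels, affine = affine,
      labels = vapply(labels, as.integer, integer(1)))
}

#' @describeIn LabelVolume binary mask of one tissue role.
#' @param x a LabelVolume.
#' @param role a name present in \code{labels(x)}.
#' @export
labelMask <- function(x, role) {
  if (!role %in% names(x@labels))
    stop("label role '", role, "' not defined for this volume")
  x@voxels == x@labels[[role]]
}

#' @describeIn LabelVolume brain mask: union of all non-background labels.
#' @export
brainMask <- function(x) {
  if (!"background" %in% names(x@labels))
    stop("volume has no background label")
  x@voxels != x@labels[["background"]]
}

setMethod("show", "LabelVolume", function(object) {
  cat("LabelVolume ", paste(dim(object@voxels), collapse = " x "),
      " voxels; labels: ",
      paste(names(object@labels), object@labels, sep = "=", collapse = ", "),
      "\n", sep = "")
})

# shift a 3D logical/numeric array by integer offsets, zero-filled
shiftArray <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

# one binary dilation with a full 3x3x3 structuring element
dilate26 <- function(mask) {
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out | shiftArray(mask, dx, dy, dz)
  }
  out
}

#' Label 26-connected components of a binary 3D mask
#'
#' Flood-fill labelling with full 26-neighbour connectivity.
#'
#' @param mask logical 3D array.
#' @return integer array of the same shape: 0 outside the mask, and the
#'   component id (1..n) inside.
#' @export
connectedComponents26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  remaining <- mask
  comp <- 0L
  while (any(remaining)) {
    comp <- comp + 1L
    seedIdx <- which(remaining)[1]
    cur <- array(FALSE, d)
    cur[seedIdx] <- TRUE
    repeat {
      grown <- dilate26(cur) & remaining
      if (sum(grown) == sum(cur)) break
      cur <- grown
    }
    lab[cur] <- comp
    remaining <- remaining & !cur
  }
  lab
}
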