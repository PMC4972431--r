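# Coordinate conventions: world = affine %*% c(i, j, k, 1) with 0-based
# voxel indices and voxel-centre sampling.  All meshes and streamlines
# live in world mm.

#' Convert world coordinates to continuous 0-based voxel indices
#' @param points numeric N x 3 matrix (or length-3 vector) of world mm.
#' @param affine 4x4 voxel-to-world transform.
#' @return numeric N x 3 matrix of continuous 0-based voxel indices.
#' @export
worldToVoxel <- function(points, affine) {
  points <- rbind3(points)
  inv <- solve(affine)
  out <- cbind(points, 1) %*% t(inv)
  out[, 1:3, drop = FALSE]
}

#' Convert 0-based voxel indices to world coordinates
#' @param ijk numeric N x 3 matrix of 0-based voxel indices.
#' @param affine 4x4 voxel-to-world transform.
#' @return numeric N x 3 matrix of world mm.
#' @export
voxelToWorld <- function(ijk, affine) {
  ijk <- rbind3(ijk)
  out <- cbind(ijk, 1) %*% t(affine)
  out[, 1:3, drop = FALSE]
}

#' Nearest 0-based voxel index for world points
#' @inheritParams worldToVoxel
#' @return integer N x 3 matrix.
#' @export
nearestVoxel <- function(points, affine) {
  v <- round(worldToVoxel(points, affine))
  storage.mode(v) <- "integer"
  v
}

# coerce a length-3 vector to a 1 x 3 matrix
rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

# look up array values at integer 0-based voxel indices; outside -> NA
voxelLookup <- function(vol, ijk) {
  d <- dim(vol)
  ijk <- rbind3(ijk)
  ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] &
        ijk[, 2] >= 0 & ijk[, 2] < d[2] &
        ijk[, 3] >= 0 & ijk[, 3] < d[3]
  out <- rep(NA_real_, nrow(ijk))
  if (any(ok)) {
    lin <- 1L + ijk[ok, 1] + d[1] * (ijk[ok, 2] + d[2] * ijk[ok, 3])
    out[ok] <- vol[lin]
  }
  out
}

# trilinear interpolation at continuous 0-based voxel coordinates
trilinear <- function(vol, xyz) {
  d <- dim(vol)
  xyz <- rbind3(xyz)
  x0 <- floor(xyz)
  fr <- xyz - x0
  out <- rep(NA_real_, nrow(xyz))
  ok <- x0[, 1] >= 0 & x0[, 1] <= d[1] - 2 &
        x0[, 2] >= 0 & x0[, 2] <= d[2] - 2 &
        x0[, 3] >= 0 & x0[, 3] <= d[3] - 2
  if (!any(ok)) return(out)
  x0 <- x0[ok, , drop = FALSE]; f <- fr[ok, , drop = FALSE]
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    lin <- 1L + (x0[, 1] + dx) + d[1] * ((x0[, 2] + dy) + d[2] * (x0[, 3] + dz))
    acc <- acc + w * vol[lin]
  }
  out[ok] <- acc
  out
}

rowNorms <- function(m) sqrt(rowSums(m * m))

normalizeRows <- function(m) {
  n <- rowNorms(m)
  n[n == 0] <- 1
  m / n
}

# deterministic integer sub-seed derived from a base seed (stays < 2^31)
subSeed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 1000003 * as.numeric(k)) %% 2147483629
}
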