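#' Construct a Tractogram
#'
#' @param streamlines list of nodes x 3 matrices (world mm).
#' @param metadata data.frame with one row per streamline.
#' @param space coordinate-space tag (default "world-mm").
#' @param provenance list of counts (requested/attempted/accepted).
#' @export
Tractogram <- function(streamlines, metadata = NULL, space = "world-mm",
                       provenance = list()) {
  if (is.null(metadata))
    metadata <- data.frame(row.names = seq_along(streamlines))
  new("Tractogram", streamlines = streamlines, metadata = metadata,
      space = space, provenance = provenance)
}

#' @describeIn Tractogram number of streamlines.
#' @param x a Tractogram.
#' @export
nTracks <- function(x) length(x@streamlines)

#' @describeIn Tractogram the list of streamline point matrices.
#' @export
trackList <- function(x) x@streamlines

#' @describeIn Tractogram per-track metadata.
#' @export
trackMetadata <- function(x) x@metadata

#' @describeIn Tractogram subset a tractogram by track index.
#' @param idx integer or logical index.
#' @export
subsetTracks <- function(x, idx) {
  md <- x@metadata[idx, , drop = FALSE]
  rownames(md) <- NULL
  new("Tractogram", streamlines = x@streamlines[idx], metadata = md,
      space = x@space, provenance = x@provenance)
}

setMethod("show", "Tractogram", function(object) {
  cat("Tractogram with", nTracks(object), "streamlines in",
      object@space, "space\n")
})

#' Construct a PlanarROI
#'
#' @param affine 4x4 voxel-to-world transform of the reference grid.
#' @param dim integer length-3 grid shape.
#' @param axis slice axis (1 = x, 2 = y, 3 = z).
#' @param sliceIndex 0-based slice index.
#' @param voxels K x 3 matrix of 0-based voxel indices on that slice.
#' @param role "thalamus", "plic", "brainstem" or "cc".
#' @export
PlanarROI <- function(affine, dim, axis, sliceIndex, voxels, role) {
  voxels <- rbind3(voxels)
  storage.mode(voxels) <- "integer"
  new("PlanarROI", affine = affine, dim = as.integer(dim),
      axis = as.integer(axis), sliceIndex = as.integer(sliceIndex),
      voxels = voxels, role = role)
}

setMethod("show", "PlanarROI", function(object) {
  cat("PlanarROI '", object@role, "': ", nrow(object@voxels),
      " voxels on slice ", object@sliceIndex, " (axis ", object@axis,
      ")\n", sep = "")
})

# linear 0-based voxel key set for fast membership
roiKeySet <- function(roi) {
  d <- roi@dim
  roi@voxels[, 1] + d[1] * (roi@voxels[, 2] + d[2] * roi@voxels[, 3])
}

# per-node membership of streamline points in an ROI (nearest voxel)
roiVisitMask <- function(points, roi) {
  ijk <- nearestVoxel(points, roi@affine)
  d <- roi@dim
  keys <- ijk[, 1] + d[1] * (ijk[, 2] + d[2] * ijk[, 3])
  inGrid <- ijk[, 1] >= 0 & ijk[, 1] < d[1] & ijk[, 2] >= 0 &
            ijk[, 2] < d[2] & ijk[, 3] >= 0 & ijk[, 3] < d[3]
  inGrid & keys %in% roiKeySet(roi)
}

#' First node of a streamline inside an ROI
#' @param points nodes x 3 matrix.
#' @param roi a [PlanarROI-class].
#' @return node index, or NA if the track never enters the ROI.
#' @export
firstNodeInROI <- function(points, roi) {
  hit <- which(roiVisitMask(points, roi))
  if (length(hit)) hit[1] else NA_integer_
}

#' World z-coordinate of a planar ROI's slice plane
#' @param roi a [PlanarROI-class].
#' @export
roiPlaneCoord <- function(roi) {
  ijk <- c(0, 0, 0)
  ijk[roi@axis] <- roi@sliceIndex
  voxelToWorld(ijk, roi@affine)[roi@axis]
}

# ---- seeding ---------------------------------------------------------------

#' Area-proportional seeding from the active surface patch
#'
#' Active triangles are those whose three vertices all survive the
#' activation mask.  For each of \code{n} draws a triangle is chosen with
#' probability proportional to its area, a point is drawn uniformly
#' inside it (square-root barycentric sampling), and the initial
#' direction is the inward triangle normal.  The caller supplies a mesh
#' already shrunk inward (the seeds then start in white matter).
#'
#' @param mesh a [SurfaceMesh-class] (the shrunk seeding mesh).
#' @param activeMask logical per-vertex activation mask.
#' @param n number of seeds.
#' @return list with \code{points} (n x 3), \code{directions} (n x 3,
#'   inward unit normals) and \code{triangle} (chosen triangle index).
#' @export
seedFromSurface <- function(mesh, activeMask, n) {
  tr <- mesh@triangles
  act <- which(activeMask[tr[, 1]] & activeMask[tr[, 2]] &
               activeMask[tr[, 3]])
  if (!length(act)) stop("empty seed region")
  areas <- triangleAreas(mesh)[act]
  pick <- act[sample.int(length(act), n, replace = TRUE, prob = areas)]
  r1 <- stats::runif(n); r2 <- stats::runif(n)
  s <- sqrt(r1)
  ba <- 1 - s; bb <- s * (1 - r2); bc <- s * r2
  v <- mesh@vertices
  pts <- ba * v[tr[pick, 1], , drop = FALSE] +
         bb * v[tr[pick, 2], , drop = FALSE] +
         bc * v[tr[pick, 3], , drop = FALSE]
  dirs <- -triangleNormals(mesh)[pick, , drop = FALSE]
  list(points = pts, directions = dirs, triangle = pick)
}

# ---- propagation -----------------------------------------------------------

# precomputed Moller-Trumbore data for a constraint mesh
constraintData <- function(mesh) {
  v <- mesh@vertices; tr <- mesh@triangles
  v0 <- v[tr[, 1], , drop = FALSE]
  list(v0 = v0,
       e1 = v[tr[, 2], , drop = FALSE] - v0,
       e2 = v[tr[, 3], , drop = FALSE] - v0)
}

# does segment p -> q cross any triangle? (vectorised Moller-Trumbore)
segmentHitsMesh <- function(p, q, cd) {
  dir <- q - p
  h <- cbind(dir[2] * cd$e2[, 3] - dir[3] * cd$e2[, 2],
             dir[3] * cd$e2[, 1] - dir[1] * cd$e2[, 3],
             dir[1] * cd$e2[, 2] - dir[2] * cd$e2[, 1])
  a <- rowSums(cd$e1 * h)
  s <- matrix(p, nrow(cd$v0), 3, byrow = TRUE) - cd$v0
  sxe1 <- cbind(s[, 2] * cd$e1[, 3] - s[, 3] * cd$e1[, 2],
                s[, 3] * cd$e1[, 1] - s[, 1] * cd$e1[, 3],
                s[, 1] * cd$e1[, 2] - s[, 2] * cd$e1[, 1])
  ok <- abs(a) > 1e-12
  f <- ifelse(ok, 1 / a, 0)
  u <- f * rowSums(s * h)
  vv <- f * (sxe1[, 1] * dir[1] + sxe1[, 2] * dir[2] + sxe1[, 3] * dir[3])
  tt <- f * rowSums(cd$e2 * sxe1)
  any(ok & u >= 0 & u <= 1 & vv >= 0 & (u + vv) <= 1 & tt >= 0 & tt <= 1)
}

#' Propagate one streamline through a direction field
#'
#' Fixed-step integration from a seed point: at each step the field is
#' queried (sign-aligned to the previous direction); a step whose turning
#' angle exceeds theta_max = 2 asin(step / (2 minRadius)) terminates the
#' track (probabilistic fields get up to \code{redraws} fresh draws
#' first).  A track also terminates on entering a voxel with FA at or
#' below \code{faCutoff} (that node is kept), when the step segment would
#' cross any triangle of the constraint mesh (the crossing point is not
#' kept), when the field has no value, or at \code{maxLength}.
#'
#' @param seed length-3 seed point (world mm).
#' @param dir0 initial unit direction.
#' @param field a direction-field function (see [uniformField()]).
#' @param fa 3D FA array (NULL disables the FA criterion).
#' @param faAffine 4x4 voxel-to-world transform of the FA grid.
#' @param constraint a [SurfaceMesh-class] or NULL.
#' @param step step size in mm (default 0.2).
#' @param minRadius minimum curvature radius in mm (default 1).
#' @param maxLength maximum track length in mm (default 250).
#' @param faCutoff FA termination threshold (default 0.1).
#' @param redraws direction redraws allowed on a curvature violation
#'   (default 50; a repeated identical draw stops redrawing early).
#' @param stopROI optional [PlanarROI-class]: the track terminates (node
#'   kept) once a node's nearest voxel enters this ROI - the brainstem
#'   termination plane of the published protocol.
#' @return list with \code{points} (nodes x 3) and \code{reason} (one of
#'   "low-fa", "mesh", "curvature", "no-direction", "stop-roi",
#'   "max-length").
#' @export
propagate <- function(seed, dir0, field, fa = NULL, faAffine = NULL,
                      constraint = NULL, step = 0.2, minRadius = 1,
                      maxLength = 250, faCutoff = 0.1, redraws = 50L,
                      stopROI = NULL) {
  if (!is.null(fa)) {
    fa0 <- voxelLookup(fa, nearestVoxel(seed, faAffine))
    if (is.na(fa0)) stop("seed outside FA volume")
  }
  thetaMax <- 2 * asin(step / (2 * minRadius))
  cosMin <- cos(thetaMax)
  cd <- if (!is.null(constraint)) constraintData(constraint) else NULL
  maxNodes <- floor(maxLength / step) + 1L
  pts <- matrix(NA_real_, maxNodes, 3)
  pts[1, ] <- seed
  pos <- seed; prev <- dir0 / sqrt(sum(dir0^2))
  nPts <- 1L
  reason <- "max-length"
  while (nPts < maxNodes) {
    d <- field(pos, prev)
    if (is.null(d)) { reason <- "no-direction"; break }
    # the curvature bound constrains turning between consecutive
    # segments; the seed direction is an inward surface normal, not a
    # field sample, so the first step is only sign-aligned to it
    if (nPts > 1L && sum(d * prev) < cosMin) {
      okDraw <- FALSE
      last <- d
      for (rd in seq_len(redraws)) {
        d2 <- field(pos, prev)
        if (is.null(d2)) break
        if (sum(d2 * prev) >= cosMin) { d <- d2; okDraw <- TRUE; break }
        if (all(d2 == last)) break  # deterministic field: no point redrawing
        last <- d2
      }
      if (!okDraw) { reason <- "curvature"; break }
    }
    newPos <- pos + step * d
    if (!is.null(cd) && segmentHitsMesh(pos, newPos, cd)) {
      reason <- "mesh"; break
    }
    nPts <- nPts + 1L
    pts[nPts, ] <- newPos
    pos <- newPos; prev <- d
    if (!is.null(fa)) {
      faHere <- voxelLookup(fa, nearestVoxel(pos, faAffine))
      if (is.na(faHere) || faHere <= faCutoff) { reason <- "low-fa"; break }
    }
    if (!is.null(stopROI) &&
        roiVisitMask(matrix(pos, 1, 3), stopROI)) {
      reason <- "stop-roi"; break
    }
  }
  list(points = pts[seq_len(nPts), , drop = FALSE], reason = reason)
}

#' Keep streamlines that follow the seeding-to-brainstem route
#'
#' A streamline passes iff it (i) visits at least one voxel of the
#' thalamus or PLIC ROI, (ii) ends with its final node inside the
#' brainstem ROI, and (iii) never visits a corpus-callosum ROI voxel.
#' Order is preserved.
#'
#' @param t a [Tractogram-class].
#' @param thalamus,plic,brainstem,cc [PlanarROI-class] objects.
#' @return the filtered [Tractogram-class].
#' @export
roiPassFilter <- function(t, thalamus, plic, brainstem, cc) {
  keep <- vapply(t@streamlines, function(pts) {
    if (any(roiVisitMask(pts, cc))) return(FALSE)
    if (!any(roiVisitMask(pts, thalamus)) &&
        !any(roiVisitMask(pts, plic))) return(FALSE)
    roiVisitMask(pts[nrow(pts), , drop = FALSE], brainstem)
  }, logical(1))
  subsetTracks(t, keep)
}

#' Generate the target number of accepted streamlines
#'
#' Repeatedly seeds from the active surface patch, propagates each seed
#' through the direction field, and keeps tracks passing the ROI filter,
#' until \code{target} tracks are accepted or \code{maxAttempts} seeds
#' are spent.  Deterministic under a fixed RNG seed.
#'
#' @param seedMesh shrunk seeding [SurfaceMesh-class].
#' @param activeMask logical per-vertex activation mask on seedMesh.
#' @param field a direction-field function.
#' @param fa 3D FA array (or NULL).
#' @param faAffine its voxel-to-world transform.
#' @param rois named list with elements thalamus, plic, brainstem, cc.
#' @param target number of tracks wanted (paper protocol: 20000).
#' @param maxAttempts seed budget (default 100 x target).
#' @param seed RNG seed (integer) or NULL to use the current RNG state.
#' @param constraint anatomically-constraining mesh (or NULL).
#' @param ... further arguments to [propagate()].
#' @return list with \code{status} ("ok" or "no tracks found"),
#'   \code{tractogram}, and counts \code{accepted}/\code{attempted}.
#' @export
generateTracks <- function(seedMesh, activeMask, field, fa, faAffine, rois,
                           target, maxAttempts = 100L * target, seed = NULL,
                           constraint = NULL, ...) {
  stopifnot(target >= 1)
  if (!is.null(seed)) set.seed(seed)
  accepted <- list()
  acceptedMeta <- NULL
  attempted <- 0L
  while (length(accepted) < target && attempted < maxAttempts) {
    batch <- min(max(target, 20L), maxAttempts - attempted)
    sd <- seedFromSurface(seedMesh, activeMask, batch)
    for (i in seq_len(batch)) {
      attempted <- attempted + 1L
      pr <- propagate(sd$points[i, ], sd$directions[i, ], field, fa,
                      faAffine, constraint = constraint, ...)
      if (nrow(pr$points) < 2L) next
      one <- Tractogram(list(pr$points))
      if (nTracks(roiPassFilter(one, rois$thalamus, rois$plic,
                                rois$brainstem, rois$cc)) == 1L) {
        accepted[[length(accepted) + 1L]] <- pr$points
        acceptedMeta <- rbind(acceptedMeta,
          data.frame(seedTriangle = sd$triangle[i], reason = pr$reason))
      }
      if (length(accepted) >= target) break
    }
  }
  prov <- list(requested = target, attempted = attempted,
               accepted = length(accepted))
  if (!length(accepted))
    return(list(status = "no tracks found",
                tractogram = Tractogram(list(), provenance = prov),
                accepted = 0L, attempted = attempted))
  tg <- Tractogram(accepted, metadata = acceptedMeta, provenance = prov)
  list(status = "ok", tractogram = tg, accepted = length(accepted),
       attempted = attempted)
}
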