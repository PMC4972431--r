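# Tract-level statistics: directional dispersion of a bundle, the
# superior/inferior split at the midbrain, FA/MD sampling along tracks,
# and hemispheric asymmetry indices adjusted for age.

# stepping directions of one track at given arc-length fractions:
# the direction of the segment leaving the interpolated position
# (the final segment at 100%)
steppingDirections <- function(points, fractions, byIndex = FALSE) {
  dp <- diff(points)
  segLen <- rowNorms(dp)
  if (any(segLen == 0)) {
    warning("zero-length segment skipped")
    keep <- c(TRUE, segLen > 0)
    points <- points[keep, , drop = FALSE]
    dp <- diff(points)
    segLen <- rowNorms(dp)
  }
  if (nrow(dp) < 1L) stop("track is fully degenerate")
  dirs <- dp / segLen
  if (byIndex) {
    idx <- pmin(1L + floor(fractions * (nrow(points) - 1L)), nrow(dp))
    return(dirs[idx, , drop = FALSE])
  }
  cum <- c(0, cumsum(segLen))
  L <- cum[length(cum)]
  s <- fractions * L
  idx <- findInterval(s, cum, rightmost.closed = FALSE)
  idx <- pmin(idx, nrow(dp))
  dirs[idx, , drop = FALSE]
}

#' Directional dispersion of a tract
#'
#' The mean squared geodesic (great-circle) deviation of per-track
#' stepping directions from the bundle's mean direction, evaluated at 20
#' positions evenly spaced along each track (0%, 5.3%, ..., 94.7%, 100%
#' of track length).  The mean direction at each position is the
#' normalised arithmetic mean of the tracks' unit stepping vectors
#' (rotation-invariant; a spherical-coordinate variant that averages
#' inclination and azimuth separately is available via \code{mode}).
#' Tightly parallel bundles give values near 0; incoherent bundles give
#' large values.  Units: radians squared.
#'
#' @param t a [Tractogram-class] with at least 2 tracks of >= 2 nodes.
#' @param nPositions number of node-positions (default 20).
#' @param mode "unit-vector" (default) or "spherical" (componentwise
#'   circular means of inclination/azimuth).
#' @param byIndex take positions as node-index fractions rather than
#'   arc-length fractions (default FALSE).
#' @return dispersion in radians^2.
#' @export
tractDispersion <- function(t, nPositions = 20L,
                            mode = c("unit-vector", "spherical"),
                            byIndex = FALSE) {
  mode <- match.arg(mode)
  nT <- nTracks(t)
  if (nT < 2L) stop("need at least two tracks")
  fractions <- seq(0, 1, length.out = nPositions)
  dirArr <- lapply(t@streamlines, steppingDirections, fractions = fractions,
                   byIndex = byIndex)
  total <- 0
  for (k in seq_len(nPositions)) {
    D <- t(vapply(dirArr, function(m) m[k, ], numeric(3)))
    if (mode == "unit-vector") {
      mu <- colMeans(D)
      nm <- sqrt(sum(mu^2))
      if (nm < 1e-12) stop("mean direction undefined at a position")
      mu <- mu / nm
      dev <- acos(pmin(pmax(D %*% mu, -1), 1))
    } else {
      theta <- acos(pmin(pmax(D[, 3], -1), 1))
      phi <- atan2(D[, 2], D[, 1])
      mth <- mean(theta)
      mph <- atan2(mean(sin(phi)), mean(cos(phi)))
      cosd <- cos(theta) * cos(mth) + sin(theta) * sin(mth) * cos(phi - mph)
      dev <- acos(pmin(pmax(cosd, -1), 1))
    }
    total <- total + sum(dev^2)
  }
  total / (nPositions * nT)
}

#' Split tracts at the midbrain plane
#'
#' Each track (ordered cortex to brainstem) is cut at its first node at
#' or below the midbrain ROI's axial plane: nodes above go to the
#' superior segment, the rest to the inferior segment.  A track entirely
#' on one side goes whole to that side with a warning.
#'
#' @param t a [Tractogram-class].
#' @param midbrainSlice a [PlanarROI-class] on an axial slice.
#' @return list of Tractograms \code{superior} and \code{inferior}; the
#'   \code{parent} metadata column records the source track.
#' @export
splitAtMidbrain <- function(t, midbrainSlice) {
  zPlane <- roiPlaneCoord(midbrainSlice)
  sup <- list(); inf <- list()
  supParent <- integer(0); infParent <- integer(0)
  oneSided <- 0L
  for (i in seq_len(nTracks(t))) {
    pts <- t@streamlines[[i]]
    below <- which(pts[, 3] <= zPlane)
    cut <- if (length(below)) below[1] else nrow(pts) + 1L
    if (cut == 1L || cut > nrow(pts)) oneSided <- oneSided + 1L
    if (cut > 1L) {
      sup[[length(sup) + 1L]] <- pts[seq_len(cut - 1L), , drop = FALSE]
      supParent <- c(supParent, i)
    }
    if (cut <= nrow(pts)) {
      inf[[length(inf) + 1L]] <- pts[cut:nrow(pts), , drop = FALSE]
      infParent <- c(infParent, i)
    }
  }
  if (oneSided > 0L)
    warning(oneSided, " track(s) lie entirely on one side of the plane")
  list(superior = Tractogram(sup, data.frame(parent = supParent),
                             space = t@space),
       inferior = Tractogram(inf, data.frame(parent = infParent),
                             space = t@space))
}

#' Mean scalar-map value along a tract
#'
#' Mean of the map value at every node of every track (nearest-voxel
#' lookup).  Nodes outside the map are excluded with a warning.
#'
#' @param t a [Tractogram-class].
#' @param map 3D scalar array (FA or MD).
#' @param affine 4x4 voxel-to-world transform of the map.
#' @return mean value; attribute \code{nOutside} counts excluded nodes.
#' @export
sampleScalar <- function(t, map, affine) {
  if (nTracks(t) == 0L) stop("empty tractogram")
  pts <- do.call(rbind, t@streamlines)
  vals <- voxelLookup(map, nearestVoxel(pts, affine))
  nOut <- sum(is.na(vals))
  if (nOut > 0L)
    warning(nOut, " node(s) outside the map were excluded")
  out <- mean(vals, na.rm = TRUE)
  attr(out, "nOutside") <- nOut
  out
}

#' Asymmetry index
#'
#' AI = (A - I) / (A + I), where A and I are the mean values for the
#' hemispheres opposite the able and impaired hands.
#'
#' @param a able-hemisphere value.
#' @param i impaired-hemisphere value.
#' @export
asymmetryIndex <- function(a, i) {
  if (a + i == 0) stop("asymmetry index undefined: a + i = 0")
  (a - i) / (a + i)
}

#' Age-adjust per-subject values
#'
#' Residuals of an ordinary least-squares fit of value on age, plus the
#' grand mean (scale preserved).  With a constant age vector the
#' adjustment is skipped with a warning.
#'
#' @param values numeric per-subject values.
#' @param ages numeric ages in years.
#' @return adjusted values.
#' @export
ageAdjust <- function(values, ages) {
  if (length(values) < 3L) stop("need at least three subjects")
  if (length(values) != length(ages)) stop("values/ages length mismatch")
  if (stats::sd(ages) == 0) {
    warning("constant age vector; adjustment skipped")
    return(values)
  }
  stats::resid(stats::lm(values ~ ages)) + mean(values)
}

#' Correlate adjusted metrics with a clinical score
#'
#' Squared Pearson correlation and the two-sided p-value of the linear
#' association.
#'
#' @param adjusted numeric per-subject (age-adjusted) metric.
#' @param scores numeric per-subject clinical score.
#' @return list with \code{R2} and \code{p}.
#' @export
correlateClinical <- function(adjusted, scores) {
  if (length(adjusted) < 3L) stop("need at least three subjects")
  if (length(adjusted) != length(scores)) stop("paired inputs required")
  if (stats::sd(adjusted) == 0 || stats::sd(scores) == 0)
    stop("zero-variance input")
  ct <- stats::cor.test(adjusted, scores)
  list(R2 = unname(ct$estimate^2), p = ct$p.value)
}
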