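# Synthetic inputs for every pipeline stage: label-volume phantoms,
# block-design EPI with injected activation, motion and AR(1) noise, and
# curved left/right streamline bundles with corticomotor vs
# thalamocortical geometry plus matched FA/MD corridors and planar ROIs.
# Every generator is a pure function of its arguments and the seed.

#' Two-hemisphere brain-like label phantom
#'
#' An ellipsoidal "brain" of grey matter with two white-matter lobes
#' separated by a mid-sagittal gap, plus planted sub-40-voxel WM islands
#' at the brain edge (for segmentation-cleanup testing).  Deterministic.
#'
#' @param dim grid shape (default c(48, 56, 48)).
#' @param voxelSize isotropic voxel size in mm (default 2).
#' @param centre world-mm centre of the brain ellipsoid (default origin).
#' @param semiAxes brain ellipsoid semi-axes in mm.
#' @param wmScale WM ellipsoid scale relative to the brain (default 0.72).
#' @param gapHalfWidth half-width of the mid-sagittal WM gap in mm.
#' @param islands number of planted edge islands (default 2, sizes 10
#'   and 39 voxels).
#' @param stalk optional brainstem stalk: a list with elements \code{x}
#'   (absolute-x band, mm), \code{y} and \code{z} ranges.  WM is added
#'   in the two mirrored boxes (the mid-sagittal gap still applies) with
#'   a grey-matter margin, so the interface mesh stays open towards the
#'   spinal cord like a real brain instead of sealing the bottom.
#' @return a [LabelVolume-class]; attribute \code{islandVoxelCount}
#'   gives the total planted island volume.
#' @export
makeBrainPhantom <- function(dim = c(48L, 56L, 48L), voxelSize = 2,
                             centre = c(0, 0, 0),
                             semiAxes = c(40, 48, 40), wmScale = 0.72,
                             gapHalfWidth = 2, islands = 2L,
                             stalk = NULL) {
  dim <- as.integer(dim)
  aff <- diag(c(rep(voxelSize, 3), 1))
  aff[1:3, 4] <- centre - voxelSize * (dim - 1) / 2
  g <- as.matrix(expand.grid(i = 0:(dim[1] - 1), j = 0:(dim[2] - 1),
                             k = 0:(dim[3] - 1)))
  w <- voxelToWorld(g, aff)
  w <- w - matrix(centre, nrow(w), 3, byrow = TRUE)
  if (any(semiAxes > voxelSize * dim / 2 - 2 * voxelSize))
    stop("grid too small to contain the phantom geometry")
  rBrain <- sqrt((w[, 1] / semiAxes[1])^2 + (w[, 2] / semiAxes[2])^2 +
                 (w[, 3] / semiAxes[3])^2)
  rWM <- sqrt((w[, 1] / (wmScale * semiAxes[1]))^2 +
              (w[, 2] / (wmScale * semiAxes[2]))^2 +
              (w[, 3] / (wmScale * semiAxes[3]))^2)
  lab <- array(0L, dim)
  lab[rBrain <= 1] <- 1L                       # GM
  lab[rWM <= 1 & abs(w[, 1]) > gapHalfWidth] <- 2L  # WM, split lobes
  if (!is.null(stalk)) {
    m <- 4  # grey-matter margin around the stalk, mm
    ww <- w + matrix(centre, nrow(w), 3, byrow = TRUE)  # world coords
    inBox <- function(pad) abs(ww[, 1]) >= max(stalk$x[1] - pad, 0.1) &
      abs(ww[, 1]) <= stalk$x[2] + pad &
      ww[, 2] >= stalk$y[1] - pad & ww[, 2] <= stalk$y[2] + pad &
      ww[, 3] >= stalk$z[1] - pad & ww[, 3] <= stalk$z[2] + pad
    lab[inBox(m) & lab == 0L] <- 1L
    lab[inBox(0) & abs(ww[, 1]) > gapHalfWidth] <- 2L
  }
  # planted WM islands in GM at the brain edge (disconnected from the
  # lobes): small voxel runs just inside the brain boundary
  islandSizes <- c(10L, 39L)[seq_len(max(islands, 0L))]
  planted <- 0L
  for (s in seq_along(islandSizes)) {
    sz <- islandSizes[s]
    cand <- which(rBrain <= 1 & rBrain > 0.93 & lab == 1L &
                  w[, 3] > 0 & (if (s == 1) w[, 2] > 0 else w[, 2] < 0))
    # grow a contiguous blob: the sz candidates nearest the first one
    d2 <- rowSums((w[cand, , drop = FALSE] -
                   matrix(w[cand[1], ], length(cand), 3, byrow = TRUE))^2)
    take <- cand[order(d2)[seq_len(sz)]]
    lab[take] <- 2L
    planted <- planted + sz
  }
  out <- LabelVolume(lab, aff,
                     labels = c(background = 0L, GM = 1L, WM = 2L))
  attr(out, "islandVoxelCount") <- planted
  out
}

#' Block-design EPI phantom with injected activation
#'
#' Builds a 4D EPI volume over the mesh's bounding box: a flat baseline
#' plus an HRF-convolved move/stop block signal restricted to voxels
#' around an activated surface patch, AR(1) temporal noise, and an
#' optional rigid motion script applied frame-by-frame (resampled with
#' nearest-neighbour lookup, as the projection itself uses).
#'
#' @param mesh the cortical [SurfaceMesh-class] (T1 space).
#' @param design a [DesignSpec-class] (default nine 30-s blocks, TR 3 s).
#' @param nFrames number of EPI frames (default 90).
#' @param amplitude activation amplitude in intensity units at regressor
#'   peak (0 disables activation).
#' @param noiseSD temporal noise standard deviation (default 1).
#' @param rho AR(1) noise coefficient (default 0.3).
#' @param patchVertex index of the patch-centre vertex (default the
#'   vertex with the largest z).
#' @param patchRadius geodesic patch radius in mm (default 10).
#' @param voxelSize EPI voxel size in mm (default 3).
#' @param baseline baseline intensity (default 100).
#' @param motion frames x 6 matrix (3 translations mm, 3 rotations rad)
#'   or NULL for a motionless scan.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list: \code{epi} (4D array), \code{affine}, \code{motion}
#'   ([MotionTrace-class]), \code{truthMask} (logical per-vertex),
#'   \code{design}.
#' @export
makeBlockEPI <- function(mesh, design = alternatingBlockDesign(),
                         nFrames = 90L, amplitude = 5, noiseSD = 1,
                         rho = 0.3, patchVertex = NULL, patchRadius = 10,
                         voxelSize = 3, baseline = 100, motion = NULL,
                         seed) {
  set.seed(seed)
  v <- meshVertices(mesh)
  lo <- apply(v, 2, min) - 3 * voxelSize
  hi <- apply(v, 2, max) + 3 * voxelSize
  d <- as.integer(ceiling((hi - lo) / voxelSize)) + 1L
  aff <- diag(c(rep(voxelSize, 3), 1)); aff[1:3, 4] <- lo
  TR <- design@TR
  frameTimes <- (seq_len(nFrames) - 1) * TR
  X <- buildDesign(design, frameTimes)
  task <- X[, attr(X, "taskColumn")]

  if (is.null(patchVertex)) patchVertex <- which.max(v[, 3])
  adj <- vertexAdjacency(mesh)
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            weighted = TRUE)
  gd <- as.vector(igraph::distances(gr, v = patchVertex))
  truthMask <- is.finite(gd) & gd <= patchRadius & amplitude != 0

  grid <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                k = 0:(d[3] - 1)))
  wg <- voxelToWorld(grid, aff)
  sigMask <- rep(FALSE, nrow(wg))
  if (any(truthMask)) {
    sigPts <- v[truthMask, , drop = FALSE] +
      vertexNormals(mesh)[truthMask, , drop = FALSE]
    for (s in seq_len(nrow(sigPts)))
      sigMask <- sigMask | (rowSums((wg - matrix(sigPts[s, ], nrow(wg), 3,
                                                 byrow = TRUE))^2) <= 9)
  }
  nVox <- prod(d)
  # AR(1) noise, stationary start
  eps <- matrix(stats::rnorm(nVox * nFrames, sd = noiseSD), nFrames, nVox)
  noise <- eps
  if (rho != 0) {
    noise[1, ] <- eps[1, ] / sqrt(1 - rho^2)
    for (f in 2:nFrames) noise[f, ] <- rho * noise[f - 1, ] + eps[f, ]
  }
  static <- rep(baseline, nVox)
  static[sigMask] <- baseline  # activation is temporal, not static
  epi <- array(0, c(d, nFrames))
  sigCol <- which(sigMask)
  for (f in seq_len(nFrames)) {
    fr <- static + noise[f, ]
    fr[sigCol] <- fr[sigCol] + amplitude * task[f]
    epi[, , , f] <- fr
  }
  if (is.null(motion)) motion <- matrix(0, nFrames, 6)
  motion <- as.matrix(motion)
  moving <- which(rowSums(abs(motion)) > 0)
  for (f in moving) {
    Tf <- rigidTransform(motion[f, 1:3], motion[f, 4:6])
    src <- cbind(wg, 1) %*% t(solve(Tf))
    ijk <- nearestVoxel(src[, 1:3, drop = FALSE], aff)
    vals <- voxelLookup(epi[, , , f], ijk)
    vals[is.na(vals)] <- baseline
    epi[, , , f] <- array(vals, d)
  }
  mt <- MotionTrace(motion[, 1:3, drop = FALSE],
                    motion[, 4:6, drop = FALSE], frameTimes)
  list(epi = epi, affine = aff, motion = mt, truthMask = truthMask,
       design = design)
}

#' Rigid-body transform from translations and rotation angles
#'
#' @param trans length-3 translation (mm).
#' @param rot length-3 rotation angles about x, y, z (radians), applied
#'   in x-y-z order.
#' @return 4x4 affine matrix.
#' @export
rigidTransform <- function(trans, rot) {
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  out <- diag(4)
  out[1:3, 1:3] <- Rz %*% Ry %*% Rx
  out[1:3, 4] <- trans
  out
}

# cubic Bezier curve resampled at (approximately) fixed arc length
bezierCurve <- function(P, step = 0.2, nFine = 2000L) {
  tt <- seq(0, 1, length.out = nFine)
  B <- outer((1 - tt)^3, P[1, ]) + outer(3 * tt * (1 - tt)^2, P[2, ]) +
       outer(3 * tt^2 * (1 - tt), P[3, ]) + outer(tt^3, P[4, ])
  s <- c(0, cumsum(rowNorms(diff(B))))
  L <- s[length(s)]
  targets <- seq(0, L, by = step)
  if (L - targets[length(targets)] > 1e-9) targets <- c(targets, L)
  out <- matrix(0, length(targets), 3)
  for (c in 1:3) out[, c] <- stats::approx(s, B[, c], xout = targets)$y
  out
}

#' Corticomotor / thalamocortical bundle phantom
#'
#' Generates left and right streamline bundles with the two tract
#' geometries (corticomotor: lateral cortex through the PLIC to the
#' anterior brainstem; thalamocortical: cortex through the thalamus
#' slice to the posterior brainstem), per-track control-point jitter,
#' matched FA/MD corridor volumes (with an optional per-hemisphere FA
#' reduction emulating a lesion), and a consistent set of planar ROIs
#' (thalamus and PLIC on the midbrain slice, brainstem, corpus
#' callosum).  Tracks run cortex to brainstem; truth labels are in the
#' tractogram metadata.
#'
#' @param nPerBundle tracks per bundle per hemisphere (default 50).
#' @param jitterSD control-point jitter SD in mm (default 1.5).
#' @param step node spacing in mm (default 0.2).
#' @param faCorridor corridor FA (default 0.55).
#' @param faBackground FA outside the corridors (default 0.25).
#' @param faReduction named or length-2 vector: FA subtracted from the
#'   corridor per hemisphere, c(left, right) (default c(0, 0)).
#' @param mdCorridor corridor MD (default 0.8, in 1e-3 mm^2/s).
#' @param mdBackground background MD (default 1.0).
#' @param voxelSize ROI/FA grid voxel size in mm (default 2).
#' @param severed hemisphere ("left"/"right"/NULL): zero out the FA
#'   corridor over a z-band so no track can reach the brainstem there.
#' @param seed RNG seed (mandatory).
#' @return list: \code{tracks} ([Tractogram-class] with truth metadata),
#'   \code{fa}, \code{md} (3D arrays), \code{affine}, \code{rois}
#'   (list: thalamus, plic, brainstem, cc, midbrain slice),
#'   \code{centrelines} (ideal curves per bundle), \code{brainCentre}.
#' @export
makeBundles <- function(nPerBundle = 50L, jitterSD = 1.5, step = 0.2,
                        faCorridor = 0.55, faBackground = 0.25,
                        faReduction = c(left = 0, right = 0),
                        mdCorridor = 0.8, mdBackground = 1.0,
                        voxelSize = 2, severed = NULL, seed) {
  set.seed(seed)
  lo <- c(-40, -40, -10); hi <- c(40, 40, 90)
  d <- as.integer((hi - lo) / voxelSize) + 1L
  aff <- diag(c(rep(voxelSize, 3), 1)); aff[1:3, 4] <- lo
  zMid <- 40; zStem <- 0

  ctrl <- function(s, class) {
    if (class == "corticomotor")
      rbind(c(s * 30, -5, 80), c(s * 16, -3, 60),
            c(s * 10, -1, 25), c(s * 5, 8, zStem))
    else
      rbind(c(s * 25, -18, 78), c(s * 12, -15, 60),
            c(s * 7, -11, 25), c(s * 5, -10, zStem))
  }
  bundles <- expand.grid(hemisphere = c("left", "right"),
                         class = c("corticomotor", "thalamocortical"),
                         stringsAsFactors = FALSE)
  centrelines <- list(); tracks <- list(); meta <- NULL
  for (b in seq_len(nrow(bundles))) {
    s <- if (bundles$hemisphere[b] == "left") -1 else 1
    P <- ctrl(s, bundles$class[b])
    centrelines[[b]] <- bezierCurve(P, step = max(step, 0.5))
    for (i in seq_len(nPerBundle)) {
      J <- matrix(stats::rnorm(8, sd = jitterSD), 4, 2)
      # corticomotor fibres fan out at the cortex, are elongated
      # antero-posteriorly at the level of the internal capsule, and
      # funnel tightly towards the medullary pyramids; thalamocortical
      # spread is closer to isotropic along the track
      if (bundles$class[b] == "corticomotor") {
        J[, 1] <- J[, 1] * c(1, 0.6, 0.35, 0.25)
        J[, 2] <- J[, 2] * c(1, 1.6, 0.7, 0.25)
      }
      Pj <- P
      Pj[, 1:2] <- P[, 1:2] + J   # jitter in x/y; keep the z profile
      pts <- bezierCurve(Pj, step = step)
      tracks[[length(tracks) + 1L]] <- pts
      meta <- rbind(meta, data.frame(hemisphere = bundles$hemisphere[b],
                                     class = bundles$class[b]))
    }
  }
  names(centrelines) <- paste(bundles$hemisphere, bundles$class, sep = ".")

  # FA / MD corridors around the ideal centrelines
  grid <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                k = 0:(d[3] - 1)))
  wg <- voxelToWorld(grid, aff)
  fa <- array(faBackground, d)
  md <- array(mdBackground, d)
  if (length(faReduction) == 1L) faReduction <- rep(faReduction, 2)
  if (is.null(names(faReduction))) names(faReduction) <- c("left", "right")
  corridorRadius <- 5
  for (b in seq_len(nrow(bundles))) {
    cl <- centrelines[[b]]
    near <- rep(FALSE, nrow(wg))
    for (j in seq(1, nrow(cl), by = 3)) {
      dd <- (wg[, 1] - cl[j, 1])^2 + (wg[, 2] - cl[j, 2])^2 +
            (wg[, 3] - cl[j, 3])^2
      near <- near | dd <= corridorRadius^2
    }
    faVal <- faCorridor - faReduction[[bundles$hemisphere[b]]]
    fa[near] <- pmax(fa[near], faVal)
    md[near] <- mdCorridor
  }
  if (!is.null(severed)) {
    s <- if (severed == "left") -1 else 1
    cut <- wg[, 3] > 15 & wg[, 3] < 30 & sign(wg[, 1]) == s
    fa[cut] <- 0.05
  }

  mkROI <- function(centres, half, zSlice, role) {
    sl <- as.integer(round((zSlice - lo[3]) / voxelSize))
    sel <- rep(FALSE, nrow(wg))
    kMatch <- grid[, 3] == sl
    for (ct in centres)
      sel <- sel | (kMatch & abs(wg[, 1] - ct[1]) <= half[1] &
                    abs(wg[, 2] - ct[2]) <= half[2])
    PlanarROI(aff, d, 3L, sl, grid[sel, , drop = FALSE], role)
  }
  rois <- list(
    thalamus = mkROI(list(c(-8, -12), c(8, -12)), c(5, 5), zMid, "thalamus"),
    plic = mkROI(list(c(-12, -2), c(12, -2)), c(4, 4), zMid, "plic"),
    brainstem = mkROI(list(c(-5, -1), c(5, -1)), c(6, 14), zStem,
                      "brainstem"),
    cc = mkROI(list(c(0, 0)), c(2.5, 12), 60, "cc"))

  tg <- Tractogram(tracks, metadata = meta,
                   provenance = list(generator = "makeBundles", seed = seed))
  list(tracks = tg, fa = fa, md = md, affine = aff, rois = rois,
       centrelines = centrelines, brainCentre = c(0, 0, zMid))
}

#' Bake a funnel direction volume from bundle centrelines
#'
#' At each grid voxel the direction points towards a position
#' \code{lookAhead} mm further along the nearest centreline, so
#' streamlines seeded anywhere within \code{support} mm are drawn onto
#' and along the bundle.  Voxels farther than \code{support} from every
#' centreline hold the zero vector (outside the field).  The result is a
#' 4D (x, y, z, 3) array usable with [peakField()] or written as NIfTI.
#'
#' @param centrelines list of nodes x 3 centreline matrices.
#' @param affine 4x4 voxel-to-world transform of the target grid.
#' @param dim integer length-3 grid shape.
#' @param support max distance from a centreline in mm (default 25).
#' @param lookAhead along-curve look-ahead in mm (default 4).
#' @return 4D numeric array of unit direction vectors.
#' @export
bakeFunnelPeaks <- function(centrelines, affine, dim, support = 25,
                            lookAhead = 4) {
  grid <- as.matrix(expand.grid(i = 0:(dim[1] - 1), j = 0:(dim[2] - 1),
                                k = 0:(dim[3] - 1)))
  wg <- voxelToWorld(grid, affine)
  bestD <- rep(Inf, nrow(wg))
  target <- matrix(0, nrow(wg), 3)
  for (cl in centrelines) {
    stepLen <- mean(rowNorms(diff(cl)))
    ahead <- max(1L, round(lookAhead / stepLen))
    for (j in seq_len(nrow(cl))) {
      dd <- (wg[, 1] - cl[j, 1])^2 + (wg[, 2] - cl[j, 2])^2 +
            (wg[, 3] - cl[j, 3])^2
      upd <- dd < bestD
      if (any(upd)) {
        bestD[upd] <- dd[upd]
        target[upd, ] <- matrix(cl[min(j + ahead, nrow(cl)), ],
                                sum(upd), 3, byrow = TRUE)
      }
    }
  }
  dir <- normalizeRows(target - wg)
  dir[sqrt(bestD) > support, ] <- 0
  array(dir, c(dim, 3L))
}
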