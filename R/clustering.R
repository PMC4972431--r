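# Streamline classification: stage 1 splits hemispheres on 4 coarse
# features; stage 2 separates corticomotor from thalamocortical tracks
# on 12 features with per-cluster weights.  Feature space is the common
# (RAS, world-mm) space of the tractogram; midline x = 0 by convention.

#' Stage-1 features of a streamline
#'
#' The X and Y coordinates of the track's first node (at the cortex) and
#' of its first node inside either midbrain ROI (thalamus or PLIC).
#'
#' @param points nodes x 3 streamline matrix.
#' @param thalamus,plic [PlanarROI-class] midbrain ROIs.
#' @return numeric length-4 feature vector.
#' @export
stage1Features <- function(points, thalamus, plic) {
  m <- midbrainEntryNode(points, thalamus, plic)
  unname(c(points[1, 1], points[1, 2], points[m, 1], points[m, 2]))
}

# first node inside either midbrain ROI; error if the track misses both
midbrainEntryNode <- function(points, thalamus, plic) {
  a <- firstNodeInROI(points, thalamus)
  b <- firstNodeInROI(points, plic)
  m <- suppressWarnings(min(a, b, na.rm = TRUE))
  if (!is.finite(m))
    stop("streamline never enters either midbrain ROI; ",
         "it should have been filtered out")
  m
}

#' Stage-2 features of a streamline
#'
#' Twelve features: midbrain-entry X and Y; X, Y, Z of the node 50 nodes
#' after (inferior to) the midbrain entry; X, Y, Z of the node 50 nodes
#' before the end; X and Y of the final node; and 0/1 flags for PLIC and
#' thalamus passage.  When a track is too short, node indices clamp to
#' the terminal node and the \code{clamped} attribute is set.
#'
#' @inheritParams stage1Features
#' @param brainstem [PlanarROI-class] (unused in the feature values, kept
#'   for interface symmetry with the classifier).
#' @return numeric length-12 vector with attribute \code{clamped}.
#' @export
stage2Features <- function(points, thalamus, plic, brainstem = NULL) {
  n <- nrow(points)
  m <- midbrainEntryNode(points, thalamus, plic)
  i50 <- m + 50L
  e50 <- n - 50L
  clamped <- i50 > n || e50 < 1L
  i50 <- min(i50, n)
  e50 <- max(e50, 1L)
  out <- unname(c(points[m, 1:2], points[i50, 1:3], points[e50, 1:3],
                  points[n, 1:2],
                  as.numeric(any(roiVisitMask(points, plic))),
                  as.numeric(any(roiVisitMask(points, thalamus)))))
  attr(out, "clamped") <- clamped
  out
}

# global cost of a labelling under per-cluster feature weights
kmeansCost <- function(F, labels, centers, weights) {
  cost <- 0
  for (c in seq_len(nrow(centers))) {
    sel <- labels == c
    if (!any(sel)) next
    d <- F[sel, , drop = FALSE] -
      matrix(centers[c, ], sum(sel), ncol(F), byrow = TRUE)
    cost <- cost + sum((d * d) %*% weights[c, ])
  }
  cost
}

#' Weighted k-means over track features
#'
#' Lloyd iterations with a per-cluster weighted squared-error cost: each
#' track joins the cluster minimising sum_f (t_f - mu_f)^2 w_f with that
#' cluster's weights; means are recomputed; convergence is zero swaps or
#' \code{maxIter} iterations.  The whole procedure restarts
#' \code{attempts} times (the supplied initialisation is used for the
#' first attempt, random distinct tracks afterwards) and the attempt
#' with the lowest global cost wins.  An attempt that empties a cluster
#' is restarted from a fresh random initialisation and still counts
#' toward the attempt budget.
#'
#' @param F numeric tracks x features matrix.
#' @param k number of clusters.
#' @param weights k x features matrix of positive weights (default all 1).
#' @param init integer vector of k track indices used as initial means
#'   for the first attempt (default random).
#' @param maxIter iteration cap per attempt (default 1000).
#' @param attempts number of restarts (default 1).
#' @param initFun optional function returning k initial track indices,
#'   used for restarts (default: uniform random distinct tracks).
#' @param exhaustivePairs for k = 2 on small problems, additionally
#'   restart Lloyd from every distinct pair of tracks (default FALSE);
#'   with n tracks this adds choose(n, 2) attempts and in practice pins
#'   the global optimum for n up to a few dozen.
#' @return a [ClusterResult-class].
#' @export
weightedKMeans <- function(F, k, weights = NULL, init = NULL,
                           maxIter = 1000L, attempts = 1L,
                           initFun = NULL, exhaustivePairs = FALSE) {
  F <- as.matrix(F)
  n <- nrow(F); p <- ncol(F)
  if (k > n) stop("k exceeds the number of tracks")
  if (is.null(weights)) weights <- matrix(1, k, p)
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == k, ncol(weights) == p, all(weights >= 0))

  runAttempt <- function(initIdx) {
    centers <- F[initIdx, , drop = FALSE]
    labels <- integer(n)
    for (it in seq_len(maxIter)) {
      D <- sapply(seq_len(k), function(c) {
        d <- F - matrix(centers[c, ], n, p, byrow = TRUE)
        as.vector((d * d) %*% weights[c, ])
      })
      newLabels <- max.col(-D, ties.method = "first")
      if (any(tabulate(newLabels, k) == 0L))
        return(NULL)  # empty cluster: caller restarts
      swapped <- any(newLabels != labels)
      labels <- newLabels
      for (c in seq_len(k))
        centers[c, ] <- colMeans(F[labels == c, , drop = FALSE])
      if (!swapped && it > 1L)
        return(list(labels = labels, centers = centers, iterations = it,
                    converged = TRUE))
    }
    list(labels = labels, centers = centers, iterations = maxIter,
         converged = FALSE)
  }

  if (is.null(initFun)) initFun <- function() sample.int(n, k)
  inits <- lapply(seq_len(attempts), function(a)
    if (a == 1L && !is.null(init)) as.integer(init) else NULL)
  if (exhaustivePairs && k == 2L)
    inits <- c(inits, unlist(lapply(seq_len(n - 1), function(a)
      lapply((a + 1):n, function(b) c(a, b))), recursive = FALSE))
  best <- NULL; bestCost <- Inf; run <- 0L
  for (initIdx in inits) {
    run <- run + 1L
    if (is.null(initIdx)) initIdx <- initFun()
    res <- runAttempt(initIdx)
    if (is.null(res)) res <- runAttempt(initFun())
    if (is.null(res)) next
    cost <- kmeansCost(F, res$labels, res$centers, weights)
    if (cost < bestCost - 1e-12) { best <- res; bestCost <- cost }
  }
  if (is.null(best)) stop("all clustering attempts emptied a cluster")
  new("ClusterResult", labels = best$labels, centers = best$centers,
      cost = bestCost, attempts = run, converged = best$converged,
      iterations = best$iterations)
}

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: k =", nrow(object@centers), "; cost =",
      format(object@cost, digits = 6), "; sizes:",
      paste(tabulate(object@labels, nrow(object@centers)), collapse = "/"),
      "\n")
})

#' Split a tractogram into left and right hemispheres
#'
#' Stage-1 k-means (4 features, uniform weights, up to two clusters,
#' random-track initial means, three attempts, best cost kept); each
#' resulting cluster is then called left- or right-hemispheric from the
#' sign of its mean midbrain X coordinate relative to the midline.  A
#' single-hemisphere input simply yields one empty output.
#'
#' @param t a [Tractogram-class] of filtered tracks.
#' @param thalamus,plic midbrain [PlanarROI-class] objects.
#' @param midline x coordinate of the mid-sagittal plane (default 0).
#' @param attempts clustering restarts (default 3).
#' @return list with Tractograms \code{left} and \code{right}.
#' @export
splitHemispheres <- function(t, thalamus, plic, midline = 0,
                             attempts = 3L) {
  if (nTracks(t) < 2L) stop("need at least two tracks")
  F <- t(vapply(t@streamlines, stage1Features, numeric(4),
                thalamus = thalamus, plic = plic))
  res <- tryCatch(weightedKMeans(F, k = 2L, attempts = attempts),
                  error = function(e) NULL)
  if (is.null(res))  # degenerate geometry: accept a single cluster
    res <- weightedKMeans(F, k = 1L, attempts = 1L)
  k <- nrow(res@centers)
  sideOf <- vapply(seq_len(k), function(c)
    ifelse(res@centers[c, 3] < midline, "left", "right"), character(1))
  trackSide <- sideOf[res@labels]
  list(left = subsetTracks(t, trackSide == "left"),
       right = subsetTracks(t, trackSide == "right"))
}

# world y threshold of the anterior third of an ROI (RAS: +y anterior)
anteriorThirdThreshold <- function(ys) max(ys) - (max(ys) - min(ys)) / 3

#' Classify one hemisphere's tracks as corticomotor or thalamocortical
#'
#' Stage-2 weighted k-means with two clusters.  The thalamocortical
#' cluster has unit weights; the corticomotor cluster down-weights the
#' midbrain Y coordinate (0.49) and up-weights the three coordinates of
#' the node 50 steps inferior to the midbrain (1.69).  The first attempt
#' is initialised with the track whose midbrain entry is nearest a point
#' 50 mm posterior to the brain centre (thalamocortical) and, among
#' tracks passing the medullary pyramids (the anterior third of the
#' brainstem ROI in Y, falling back to the anterior third of all tracks'
#' terminal nodes when none qualify), the track farthest from that point
#' (corticomotor); ties go to the lowest track index.  Twenty attempts
#' are run (random initialisations after the first) and the lowest
#' global cost wins.  Cluster 1 is thalamocortical, cluster 2
#' corticomotor.
#'
#' @param hemi a [Tractogram-class] of one hemisphere's tracks.
#' @param thalamus,plic,brainstem [PlanarROI-class] objects.
#' @param brainCentre length-3 world point; centroid of the brain mask.
#' @param attempts restarts (default 20).
#' @return a [ClusterResult-class]; labels 1 = thalamocortical,
#'   2 = corticomotor (also in attribute \code{labelNames}).
#' @export
classifyMotorThalamic <- function(hemi, thalamus, plic, brainstem,
                                  brainCentre = c(0, 0, 0),
                                  attempts = 20L) {
  n <- nTracks(hemi)
  feats <- lapply(hemi@streamlines, stage2Features, thalamus = thalamus,
                  plic = plic, brainstem = brainstem)
  F <- t(vapply(feats, as.numeric, numeric(12)))
  posteriorPoint <- brainCentre + c(0, -50, 0)
  entryIdx <- vapply(hemi@streamlines, midbrainEntryNode, integer(1),
                     thalamus = thalamus, plic = plic)
  entryPts <- t(vapply(seq_len(n), function(i)
    hemi@streamlines[[i]][entryIdx[i], ], numeric(3)))
  dPost <- rowNorms(entryPts -
                    matrix(posteriorPoint, n, 3, byrow = TRUE))

  # medullary pyramids: anterior third of the brainstem ROI in y
  roiY <- voxelToWorld(brainstem@voxels, brainstem@affine)[, 2]
  yThr <- anteriorThirdThreshold(roiY)
  antVox <- brainstem@voxels[roiY >= yThr, , drop = FALSE]
  pyramids <- PlanarROI(brainstem@affine, brainstem@dim, brainstem@axis,
                        brainstem@sliceIndex, antVox, "brainstem")
  eligible <- vapply(hemi@streamlines, function(p)
    any(roiVisitMask(p, pyramids)), logical(1))
  if (!any(eligible)) {
    endY <- vapply(hemi@streamlines, function(p) p[nrow(p), 2], numeric(1))
    eligible <- endY >= anteriorThirdThreshold(endY)
  }
  if (!any(eligible)) eligible <- rep(TRUE, n)
  tcSeed <- which.min(dPost)
  cmSeed <- which(eligible)[which.max(dPost[eligible])]

  weights <- rbind(rep(1, 12),
                   c(1, 0.49, 1.69, 1.69, 1.69, 1, 1, 1, 1, 1, 1, 1))
  if (n < 2L) {
    warning("fewer than two tracks; single-cluster result")
    lab <- if (eligible[1]) 2L else 1L
    res <- new("ClusterResult", labels = lab,
               centers = rbind(F[1, ]), cost = 0, attempts = 0L,
               converged = TRUE, iterations = 0L)
    attr(res, "labelNames") <- c("thalamocortical", "corticomotor")
    return(res)
  }
  init <- c(tcSeed, cmSeed)
  if (tcSeed == cmSeed) init <- NULL  # degenerate: fall back to random
  # random restarts are ordered canonically: the seed nearer the
  # posterior point initialises the thalamocortical (unit-weight)
  # cluster, so cluster identity is consistent across attempts
  initFun <- function() {
    idx <- sample.int(n, 2L)
    idx[order(dPost[idx])]
  }
  res <- weightedKMeans(F, k = 2L, weights = weights, init = init,
                        attempts = attempts, initFun = initFun)
  attr(res, "labelNames") <- c("thalamocortical", "corticomotor")
  attr(res, "clamped") <- vapply(feats, function(f)
    isTRUE(attr(f, "clamped")), logical(1))
  res
}
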