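#' Construct a MotionTrace
#'
#' @param translations frames x 3 matrix of translations (mm).
#' @param rotations frames x 3 matrix of rotations (radians).
#' @param frameTimes frame acquisition times (s); defaults to 0, TR, ...
#'   with TR = 1 if not supplied.
#' @param TR repetition time used to build default frame times.
#' @export
MotionTrace <- function(translations, rotations,
                        frameTimes = NULL, TR = 1) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  if (is.null(frameTimes))
    frameTimes <- (seq_len(nrow(translations)) - 1) * TR
  new("MotionTrace", translations = translations, rotations = rotations,
      frameTimes = frameTimes)
}

setMethod("show", "MotionTrace", function(object) {
  cat("MotionTrace with", nrow(object@translations), "frames\n")
})

#' Framewise displacement
#'
#' Per-frame head motion summary (Power et al.): the sum of absolute
#' frame-to-frame differentials of the six rigid parameters, with
#' rotations converted to arc length on a sphere of radius
#' \code{headRadius}.  The first frame has FD 0.
#'
#' @param m a [MotionTrace-class].
#' @param headRadius head radius in mm (default 50).
#' @return numeric vector of FD values (mm), one per frame.
#' @export
framewiseDisplacement <- function(m, headRadius = 50) {
  if (nrow(m@translations) < 2L) stop("need at least two frames")
  if (!all(is.finite(m@translations)) || !all(is.finite(m@rotations)))
    stop("non-finite motion parameters")
  dt <- abs(diff(m@translations))
  dr <- abs(diff(m@rotations)) * headRadius
  c(0, rowSums(dt) + rowSums(dr))
}

#' Censor high-motion frames
#'
#' Frames with framewise displacement above \code{threshold} are
#' rejected.  When the total number of rejected frames across all
#' supplied scans reaches \code{maxRejected} or more, the dataset as a
#' whole is rejected instead of returning masks.
#'
#' @param fd a numeric FD vector, or a list of FD vectors (one per scan).
#' @param threshold FD rejection threshold in mm (default 0.9).
#' @param maxRejected dataset-rejection cutoff: this many rejected frames
#'   or more across the supplied scans rejects the dataset (default 20).
#' @return list with \code{status} ("ok" or "rejected"), \code{keptMasks}
#'   (list of logical per-frame masks, NULL when rejected) and
#'   \code{nRejected} (total rejected frame count).
#' @export
censorFrames <- function(fd, threshold = 0.9, maxRejected = 20L) {
  if (!is.list(fd)) fd <- list(fd)
  masks <- lapply(fd, function(v) v <= threshold)
  nRej <- sum(vapply(masks, function(m) sum(!m), integer(1)))
  if (nRej >= maxRejected)
    list(status = "rejected", keptMasks = NULL, nRejected = nRej)
  else
    list(status = "ok", keptMasks = masks, nRejected = nRej)
}

#' Project an EPI time series onto mesh vertices
#'
#' The mesh (in T1 space) is expanded outwards by \code{offset} mm along
#' its vertex normals to sample grey matter, transformed into EPI space,
#' and each vertex reads the nearest EPI voxel at every frame.  Vertices
#' mapping outside the field of view get NA.
#'
#' @param epi 4D numeric array (x, y, z, frames).
#' @param epiAffine 4x4 voxel-to-world transform of the EPI grid.
#' @param mesh a [SurfaceMesh-class] in T1 space.
#' @param T_epi_from_t1 4x4 affine taking T1-space mm to EPI-space mm.
#' @param offset outward sampling offset in mm (default 1).
#' @param TR repetition time (s), used for frame times (default 3).
#' @return a [VertexSeries-class] (frames x vertices), all frames kept.
#' @export
projectToSurface <- function(epi, epiAffine, mesh,
                             T_epi_from_t1 = diag(4), offset = 1, TR = 3) {
  d <- dim(epi)
  stopifnot(length(d) == 4L)
  sampMesh <- applyTransform(offsetMesh(mesh, offset), T_epi_from_t1)
  ijk <- nearestVoxel(sampMesh@vertices, epiAffine)
  inFov <- ijk[, 1] >= 0 & ijk[, 1] < d[1] &
           ijk[, 2] >= 0 & ijk[, 2] < d[2] &
           ijk[, 3] >= 0 & ijk[, 3] < d[3]
  if (!any(inFov)) stop("no vertex maps inside the EPI volume")
  nFrames <- d[4]
  dat <- matrix(NA_real_, nFrames, nVertices(mesh))
  lin <- 1L + ijk[inFov, 1] + d[1] * (ijk[inFov, 2] + d[2] * ijk[inFov, 3])
  frameLen <- prod(d[1:3])
  for (f in seq_len(nFrames))
    dat[f, inFov] <- epi[lin + (f - 1L) * frameLen]
  new("VertexSeries", data = dat, frameTimes = (seq_len(nFrames) - 1) * TR,
      keptMask = rep(TRUE, nFrames), mesh = mesh)
}

#' Heat-kernel smoothing of vertex fields along the surface
#'
#' Laplace-Beltrami diffusion of per-vertex values over the mesh, run to
#' total diffusion time t = fwhm^2 / (16 ln 2) so the equivalent planar
#' kernel has the requested full width at half maximum.  Integration uses
#' unconditionally stable backward-Euler substeps of the cotangent
#' Laplacian with lumped vertex-area masses; the surface integral of the
#' field (area-weighted mean) is conserved exactly and constant fields
#' pass through unchanged.  Smoothing respects the mesh geometry only:
#' values do not leak between points that are close in space but far
#' along the surface (opposite sulcal banks).
#'
#' @param x a [VertexSeries-class], or a numeric vector/matrix of
#'   per-vertex values (vertices in columns when a matrix is frames x
#'   vertices).
#' @param fwhm smoothing kernel FWHM in mm (default 8).
#' @param mesh required when \code{x} is not a VertexSeries.
#' @param substeps backward-Euler substeps (default 20).
#' @return object of the same shape as \code{x}, smoothed frame-wise.
#' @export
smoothOnSurface <- function(x, fwhm = 8, mesh = NULL, substeps = 20L) {
  if (fwhm <= 0) stop("fwhm must be positive")
  isSeries <- is(x, "VertexSeries")
  if (isSeries) { mesh <- x@mesh; vals <- t(x@data) } else {
    if (is.null(mesh)) stop("mesh required")
    vals <- if (is.null(dim(x))) matrix(x, ncol = 1) else t(x)
  }
  lap <- meshLaplacian(mesh)
  iso <- lap$mass <= 1e-10 | Matrix::diag(lap$L) == 0
  if (any(iso & Matrix::diag(lap$L) == 0))
    warning("disconnected vertices present; their values are unchanged")
  tTot <- fwhm^2 / (16 * log(2))
  dt <- tTot / substeps
  M <- Matrix::Diagonal(x = lap$mass)
  A <- M + dt * lap$L
  ch <- Matrix::Cholesky(methods::as(A, "symmetricMatrix"), LDL = FALSE)
  nas <- is.na(vals)
  vals[nas] <- 0
  for (s in seq_len(substeps))
    vals <- as.matrix(Matrix::solve(ch, M %*% vals))
  vals[nas] <- NA_real_
  if (isSeries)
    new("VertexSeries", data = t(vals), frameTimes = x@frameTimes,
        keptMask = x@keptMask, mesh = mesh)
  else if (is.null(dim(x))) as.vector(vals) else t(vals)
}

#' Canonical double-gamma haemodynamic response function
#'
#' Peak at 6 s, undershoot at 16 s, undershoot ratio 1/6, 32 s support
#' (the SPM canonical HRF).
#'
#' @param t time in seconds.
#' @return HRF values (unit peak area convention of dgamma differences).
#' @export
canonicalHRF <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
       stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0 | t > 32] <- 0
  h
}

#' Construct a DesignSpec
#'
#' @param moveOnsets onsets (s) of the 'move' blocks.
#' @param blockDuration duration (s) of each block (default 30).
#' @param TR repetition time (s, default 3).
#' @param highpass high-pass cutoff (s, default 120).
#' @export
DesignSpec <- function(moveOnsets, blockDuration = 30, TR = 3,
                       highpass = 120) {
  new("DesignSpec", moveOnsets = as.numeric(moveOnsets),
      blockDuration = blockDuration, TR = TR, highpass = highpass)
}

#' Alternating move/stop block design
#'
#' Nine 30-second blocks alternating stop/move (starting with 'stop'),
#' the acquisition protocol emulated throughout the package.
#'
#' @param nBlocks total number of blocks (default 9).
#' @param blockDuration seconds per block (default 30).
#' @param TR repetition time (default 3).
#' @export
alternatingBlockDesign <- function(nBlocks = 9, blockDuration = 30, TR = 3) {
  onsets <- blockDuration * seq(1, nBlocks - 1, by = 2)
  DesignSpec(onsets, blockDuration = blockDuration, TR = TR)
}

#' Build the GLM design matrix
#'
#' Columns: the HRF-convolved move-vs-stop regressor, three rotation
#' covariates, a discrete-cosine high-pass set for the design's cutoff, and
#' an intercept.  All regressors are built on the full frame grid (frame
#' times carry the temporal information, so uneven retained spacing is
#' handled correctly), then censored rows are deleted - no interpolation.
#' Constant-zero covariate columns are dropped with a warning.
#'
#' @param spec a [DesignSpec-class].
#' @param frameTimes full-grid frame times (s).
#' @param keptMask logical per-frame mask (default all kept).
#' @param rotations frames x 3 rotation parameters, or a
#'   [MotionTrace-class]; NULL omits motion covariates.
#' @return numeric design matrix (kept frames x columns) with column
#'   names; attribute \code{taskColumn} gives the task column index.
#' @export
buildDesign <- function(spec, frameTimes, keptMask = NULL, rotations = NULL) {
  n <- length(frameTimes)
  if (is.null(keptMask)) keptMask <- rep(TRUE, n)
  if (!any(keptMask)) stop("all frames are censored")
  if (is(rotations, "MotionTrace")) rotations <- rotations@rotations
  # HRF-convolved boxcar on a fine grid, sampled at frame times
  dt <- 0.1
  tMax <- max(frameTimes) + spec@TR
  fine <- seq(0, tMax, by = dt)
  box <- rep(0, length(fine))
  for (on in spec@moveOnsets)
    box[fine >= on & fine < on + spec@blockDuration] <- 1
  hk <- canonicalHRF(seq(0, 32, by = dt))
  conv <- stats::convolve(box, rev(hk), type = "open")[seq_along(fine)] * dt
  task <- stats::approx(fine, conv, xout = frameTimes, rule = 2)$y
  X <- cbind(task = task)
  if (!is.null(rotations)) {
    rot <- as.matrix(rotations)
    colnames(rot) <- paste0("rot", seq_len(ncol(rot)))
    X <- cbind(X, rot)
  }
  Ttot <- max(frameTimes) - min(frameTimes) + spec@TR
  K <- floor(2 * Ttot / spec@highpass)
  if (K >= 1) {
    tt <- frameTimes - min(frameTimes)
    dct <- sapply(seq_len(K), function(k) cos(pi * k * (tt + spec@TR / 2) / Ttot))
    colnames(dct) <- paste0("hpf", seq_len(K))
    X <- cbind(X, dct)
  }
  X <- cbind(X, intercept = 1)
  zero <- apply(X, 2, function(col) all(col == 0))
  if (any(zero)) {
    warning("dropping constant-zero columns: ",
            paste(colnames(X)[zero], collapse = ", "))
    X <- X[, !zero, drop = FALSE]
  }
  X <- X[keptMask, , drop = FALSE]
  attr(X, "taskColumn") <- match("task", colnames(X))
  X
}

#' Fit the vertex-wise GLM with AR(1) prewhitening
#'
#' Ordinary least squares per vertex; residual temporal autocorrelation
#' is modelled as AR(1) with one global coefficient pooled over vertices
#' from the first pass, the model is prewhitened and re-fit, and the
#' move-minus-stop contrast (the task column) is converted to a t
#' statistic.  Censored frames must already be removed from the design;
#' the kept-frame sequence is treated as contiguous for whitening (so a
#' fit after censoring equals a fit on data that never contained those
#' frames).  Vertices with any missing value (outside the EPI field of
#' view) are excluded and get NA statistics.
#'
#' @param series a [VertexSeries-class].
#' @param design design matrix from [buildDesign()] (rows = kept frames).
#' @return a [VertexStatMap-class].
#' @export
fitGLM <- function(series, design) {
  Y <- series@data[series@keptMask, , drop = FALSE]
  if (nrow(Y) != nrow(design))
    stop("design rows must equal kept frame count")
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    bad <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  ok <- apply(Y, 2, function(col) all(is.finite(col)) && stats::sd(col) >= 0)
  taskCol <- attr(design, "taskColumn")
  nV <- ncol(Y)
  beta <- tstat <- rep(NA_real_, nV)

  fitPass <- function(X, Yk) {
    qx <- qr(X)
    B <- qr.coef(qx, Yk)
    E <- Yk - X %*% B
    list(qx = qx, B = B, E = E)
  }
  Yk <- Y[, ok, drop = FALSE]
  lag1 <- function(E) {
    den <- sum(colSums(E^2))
    if (den <= 0) return(0)
    sum(colSums(E[-1, , drop = FALSE] * E[-nrow(E), , drop = FALSE])) / den
  }
  W <- function(M, rho) {
    out <- M
    out[1, ] <- sqrt(1 - rho^2) * M[1, ]
    out[-1, ] <- M[-1, , drop = FALSE] - rho * M[-nrow(M), , drop = FALSE]
    out
  }
  # pooled AR(1) coefficient: the raw residual lag-1 correlation is
  # biased because the projection absorbs autocorrelation, so match the
  # observed value against its expectation tr(RAR V(rho)) / tr(R V(rho))
  # under the residual-forming matrix R and solve for rho
  p1 <- fitPass(design, Yk)
  r1obs <- lag1(p1$E)
  nF <- nrow(design)
  R <- diag(nF) - design %*% chol2inv(qr.R(p1$qx)) %*% t(design)
  A <- matrix(0, nF, nF)
  A[cbind(1:(nF - 1), 2:nF)] <- 0.5
  A <- A + t(A)
  RAR <- R %*% A %*% R
  expLag1 <- function(rho) {
    V <- rho^abs(outer(1:nF, 1:nF, "-"))
    sum(RAR * V) / sum(R * V)
  }
  rho <- if (abs(r1obs - expLag1(0)) < 1e-12) 0 else
    tryCatch(stats::uniroot(function(r) expLag1(r) - r1obs,
                            lower = -0.9, upper = 0.95,
                            tol = 1e-5)$root,
             error = function(e) max(min(r1obs, 0.95), -0.9))
  p2 <- fitPass(W(design, rho), W(Yk, rho))
  df <- nrow(design) - ncol(design)
  XtXinv <- chol2inv(qr.R(p2$qx))
  cvar <- XtXinv[taskCol, taskCol]
  sigma2 <- colSums(p2$E^2) / df
  b <- p2$B[taskCol, ]
  beta[ok] <- b
  tstat[ok] <- b / sqrt(pmax(sigma2 * cvar, 1e-300))
  tstat[ok][sigma2 == 0] <- NA_real_
  new("VertexStatMap", beta = beta, tstat = tstat, df = df, arCoef = rho)
}

setMethod("show", "VertexStatMap", function(object) {
  cat("VertexStatMap:", length(object@tstat), "vertices; df =", object@df,
      "; AR(1) rho =", format(object@arCoef, digits = 3), "\n")
})

#' Family-wise error thresholding (Bonferroni over vertices)
#'
#' A vertex is significant iff its two-sided uncorrected p-value is at
#' most \code{alpha} divided by the number of tested vertices.
#'
#' @param stats a [VertexStatMap-class].
#' @param alpha family-wise error level (default 0.05).
#' @return logical per-vertex mask.
#' @export
thresholdFWE <- function(stats, alpha = 0.05) {
  tested <- is.finite(stats@tstat)
  p <- 2 * stats::pt(-abs(stats@tstat), df = stats@df)
  mask <- tested & p <= alpha / sum(tested)
  mask[!tested] <- FALSE
  mask
}

#' Filter activation clusters on the mesh
#'
#' Connected components of the vertex mask on the triangle-edge
#' adjacency graph; components with fewer than 3 vertices are discarded;
#' of the rest, the named components are kept.  Components are ordered
#' by size (descending), ties broken by lowest vertex index.
#'
#' @param mask logical per-vertex mask.
#' @param mesh the [SurfaceMesh-class].
#' @param selection integer component ids into the deterministic
#'   ordering, or a length-3 world point (the nearest surviving component
#'   is kept), or "all".
#' @param minVertices minimum component size (default 3).
#' @return logical per-vertex mask of the selected components.
#' @export
filterClusters <- function(mask, mesh, selection = "all", minVertices = 3L) {
  out <- rep(FALSE, nVertices(mesh))
  ids <- which(mask)
  if (!length(ids)) return(out)
  adj <- vertexAdjacency(mesh)
  sub <- adj[ids, ids, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  comps <- split(ids, comp)
  comps <- comps[vapply(comps, length, integer(1)) >= minVertices]
  if (!length(comps)) return(out)
  sizes <- vapply(comps, length, integer(1))
  minIdx <- vapply(comps, min, integer(1))
  ord <- order(-sizes, minIdx)
  comps <- comps[ord]
  keep <- if (identical(selection, "all")) {
    seq_along(comps)
  } else if (is.double(selection) && length(selection) == 3) {
    # a world-mm point: keep the nearest surviving component

    d <- vapply(comps, function(vv)
      min(rowNorms(mesh@vertices[vv, , drop = FALSE] -
                   matrix(selection, length(vv), 3, byrow = TRUE))),
      numeric(1))
    which.min(d)
  } else {
    sel <- as.integer(selection)
    if (any(sel < 1L | sel > length(comps)))
      stop("selection names a nonexistent component")
    sel
  }
  out[unlist(comps[keep])] <- TRUE
  out
}

#' Combine two task masks with logical OR
#'
#' @param m1,m2 logical per-vertex masks over the same mesh.
#' @return logical per-vertex mask.
#' @export
combineTaskMasks <- function(m1, m2) {
  if (length(m1) != length(m2))
    stop("masks have mismatched vertex counts")
  m1 | m2
}
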