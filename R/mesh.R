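#' Construct a SurfaceMesh
#'
#' @param vertices numeric N x 3 matrix of world-mm vertex positions.
#' @param triangles integer M x 3 matrix of 1-based vertex indices.
#' @return a [SurfaceMesh-class].
#' @export
SurfaceMesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  new("SurfaceMesh", vertices = vertices, triangles = triangles)
}

#' @describeIn SurfaceMesh number of vertices.
#' @param x a SurfaceMesh.
#' @export
nVertices <- function(x) nrow(x@vertices)

#' @describeIn SurfaceMesh number of triangles.
#' @export
nTriangles <- function(x) nrow(x@triangles)

#' @describeIn SurfaceMesh vertex coordinate matrix.
#' @export
meshVertices <- function(x) x@vertices

#' @describeIn SurfaceMesh triangle index matrix.
#' @export
meshTriangles <- function(x) x@triangles

setMethod("show", "SurfaceMesh", function(object) {
  cat("SurfaceMesh with", nVertices(object), "vertices and",
      nTriangles(object), "triangles; mean edge length",
      if (nTriangles(object) > 0)
        format(meanEdgeLength(object), digits = 4) else NA, "mm\n")
})

# per-triangle (unnormalised) normals: cross product, |n| = 2 * area
triangleCross <- function(mesh) {
  v <- mesh@vertices; tr <- mesh@triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Per-triangle areas (mm^2)
#' @param mesh a SurfaceMesh.
#' @export
triangleAreas <- function(mesh) rowNorms(triangleCross(mesh)) / 2

#' Total surface area (mm^2)
#' @param mesh a SurfaceMesh.
#' @export
surfaceArea <- function(mesh) sum(triangleAreas(mesh))

#' Per-triangle outward unit normals
#' @param mesh a SurfaceMesh.
#' @export
triangleNormals <- function(mesh) normalizeRows(triangleCross(mesh))

#' Per-vertex outward unit normals
#'
#' Area-weighted average of incident triangle normals.
#'
#' @param mesh a SurfaceMesh.
#' @return numeric N x 3 matrix of unit normals.
#' @export
vertexNormals <- function(mesh) {
  cr <- triangleCross(mesh)  # already area-weighted
  tr <- mesh@triangles
  idx <- c(tr[, 1], tr[, 2], tr[, 3])
  acc <- rowsum(rbind(cr, cr, cr), idx)
  out <- matrix(0, nVertices(mesh), 3)
  out[as.integer(rownames(acc)), ] <- acc
  normalizeRows(out)
}

#' Unique undirected mesh edges
#' @param mesh a SurfaceMesh.
#' @return integer E x 2 matrix, each row an edge with smaller index first.
#' @export
meshEdges <- function(mesh) {
  tr <- mesh@triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Mean vertex-to-neighbour edge length (mm)
#' @param mesh a SurfaceMesh.
#' @export
meanEdgeLength <- function(mesh) {
  e <- meshEdges(mesh)
  mean(rowNorms(mesh@vertices[e[, 1], , drop = FALSE] -
                mesh@vertices[e[, 2], , drop = FALSE]))
}

#' Vertex adjacency graph
#'
#' Vertices are adjacent iff they share a triangle edge; edge weights are
#' Euclidean lengths in mm.
#'
#' @param mesh a SurfaceMesh.
#' @return a sparse symmetric [Matrix::sparseMatrix] whose nonzero
#'   entries are edge lengths.
#' @export
vertexAdjacency <- function(mesh) {
  e <- meshEdges(mesh)
  len <- rowNorms(mesh@vertices[e[, 1], , drop = FALSE] -
                  mesh@vertices[e[, 2], , drop = FALSE])
  n <- nVertices(mesh)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = c(len, len), dims = c(n, n))
}

#' Is every edge shared by exactly two triangles?
#' @param mesh a SurfaceMesh.
#' @export
isClosedMesh <- function(mesh) {
  tr <- mesh@triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# ---- white-matter segmentation cleanup -------------------------------------

#' Remove spurious white-matter islands near the brain edge
#'
#' The inverted brain mask is dilated three times (3x3x3 cube); every
#' 26-connected cluster of WM voxels that touches this dilated mask and
#' is smaller than 40 voxels is relabelled as grey matter.  All other
#' voxels are unchanged.
#'
#' @param seg a [LabelVolume-class] with WM, GM and background labels.
#' @param minVoxels clusters smaller than this (default 40) are eligible.
#' @param dilations number of dilation passes (default 3).
#' @return a cleaned [LabelVolume-class].
#' @export
cleanWMSegmentation <- function(seg, minVoxels = 40L, dilations = 3L) {
  if (!all(c("WM", "GM") %in% names(seg@labels)))
    stop("segmentation must define WM and GM labels")
  edge <- !brainMask(seg)
  for (i in seq_len(dilations)) edge <- dilate26(edge)
  wm <- labelMask(seg, "WM")
  comp <- connectedComponents26(wm)
  out <- seg@voxels
  for (id in seq_len(max(comp, 0L))) {
    sel <- comp == id
    if (sum(sel) < minVoxels && any(edge & sel))
      out[sel] <- seg@labels[["GM"]]
  }
  new("LabelVolume", voxels = out, affine = seg@affine, labels = seg@labels)
}

# ---- marching tetrahedra isosurface ----------------------------------------

# cube corner offsets (0-based), and the 6-tetrahedra split along the
# 1..7 diagonal
.mcCorners <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                    c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
.mcTets <- rbind(c(1,2,3,7), c(1,3,4,7), c(1,4,8,7),
                 c(1,8,5,7), c(1,5,6,7), c(1,6,2,7))

# case table: for each inside-pattern of a tetrahedron, the triangles to
# emit, each triangle a 3 x 2 matrix of (inside?, any) corner pairs whose
# connecting edges carry the interpolated surface vertices
.tetCaseTable <- local({
  tab <- vector("list", 16L)
  for (ci in 0:15) {
    ins <- which(bitwAnd(ci, c(1L, 2L, 4L, 8L)) > 0)
    outs <- setdiff(1:4, ins)
    tab[[ci + 1L]] <-
      if (length(ins) %in% c(0L, 4L)) list()
      else if (length(ins) == 1L)
        list(rbind(c(ins, outs[1]), c(ins, outs[2]), c(ins, outs[3])))
      else if (length(ins) == 3L)
        list(rbind(c(ins[1], outs), c(ins[2], outs), c(ins[3], outs)))
      else {
        a <- ins[1]; b <- ins[2]; cc <- outs[1]; dd <- outs[2]
        list(rbind(c(a, cc), c(a, dd), c(b, dd)),
             rbind(c(a, cc), c(b, dd), c(b, cc)))
      }
  }
  tab
})

# isosurface of a 3D scalar field by marching tetrahedra; returns
# vertices in continuous 0-based grid coordinates plus triangles.
# Triangle orientation is fixed afterwards against the field gradient so
# normals point towards decreasing field values.
marchingTetrahedra <- function(field, level = 0.5) {
  d <- dim(field)
  nc <- d - 1L
  if (any(nc < 1L)) stop("field too small")
  # base (0-based) indices of all cubes
  bi <- as.matrix(expand.grid(i = 0:(nc[1] - 1), j = 0:(nc[2] - 1),
                              k = 0:(nc[3] - 1)))
  cornerVal <- matrix(0, nrow(bi), 8)
  for (c8 in 1:8) {
    off <- .mcCorners[c8, ]
    lin <- 1L + (bi[, 1] + off[1]) + d[1] * ((bi[, 2] + off[2]) +
           d[2] * (bi[, 3] + off[3]))
    cornerVal[, c8] <- field[lin]
  }
  active <- which(apply(cornerVal > level, 1, any) &
                  apply(cornerVal <= level, 1, any))
  if (!length(active)) stop("isosurface is empty at this level")
  bi <- bi[active, , drop = FALSE]
  cornerVal <- cornerVal[active, , drop = FALSE]

  vertChunks <- list(); triCount <- 0L
  for (t6 in seq_len(nrow(.mcTets))) {
    corn <- .mcTets[t6, ]
    V <- cornerVal[, corn, drop = FALSE]
    insideBits <- (V[, 1] > level) + 2L * (V[, 2] > level) +
                  4L * (V[, 3] > level) + 8L * (V[, 4] > level)
    for (ci in 1:14) {
      rows <- which(insideBits == ci)
      if (!length(rows)) next
      for (tri in .tetCaseTable[[ci + 1L]]) {
        # interpolate the three edge vertices for all selected cubes
        pts <- vector("list", 3L)
        for (e in 1:3) {
          p <- tri[e, 1]; q <- tri[e, 2]
          vp <- V[rows, p]; vq <- V[rows, q]
          tt <- (level - vp) / (vq - vp)
          P <- bi[rows, , drop = FALSE] +
            matrix(.mcCorners[corn[p], ], length(rows), 3, byrow = TRUE)
          Q <- bi[rows, , drop = FALSE] +
            matrix(.mcCorners[corn[q], ], length(rows), 3, byrow = TRUE)
          pts[[e]] <- P + tt * (Q - P)
        }
        # interleave rows so consecutive triples form triangles
        block <- matrix(0, 3L * length(rows), 3L)
        block[seq(1, nrow(block), 3), ] <- pts[[1]]
        block[seq(2, nrow(block), 3), ] <- pts[[2]]
        block[seq(3, nrow(block), 3), ] <- pts[[3]]
        vertChunks[[length(vertChunks) + 1L]] <- block
        triCount <- triCount + length(rows)
      }
    }
  }
  allPts <- do.call(rbind, vertChunks)
  tris <- matrix(seq_len(3L * triCount), ncol = 3, byrow = TRUE)
  m <- weldMeshVertices(allPts, tris)
  orientAgainstGradient(m$vertices, m$triangles, field, level)
}

# merge coincident vertices (rounded grid coordinates) and drop
# degenerate triangles
weldMeshVertices <- function(pts, tris, digits = 6L) {
  key <- paste(round(pts[, 1], digits), round(pts[, 2], digits),
               round(pts[, 3], digits))
  ukey <- unique(key)
  vid <- match(key, ukey)
  verts <- pts[match(ukey, key), , drop = FALSE]
  tris <- matrix(vid[tris], ncol = 3)
  good <- tris[, 1] != tris[, 2] & tris[, 2] != tris[, 3] &
          tris[, 1] != tris[, 3]
  list(vertices = verts, triangles = tris[good, , drop = FALSE])
}

# flip triangles whose normal points towards increasing field values
orientAgainstGradient <- function(verts, tris, field, level) {
  cent <- (verts[tris[, 1], , drop = FALSE] + verts[tris[, 2], , drop = FALSE] +
           verts[tris[, 3], , drop = FALSE]) / 3
  a <- verts[tris[, 2], , drop = FALSE] - verts[tris[, 1], , drop = FALSE]
  b <- verts[tris[, 3], , drop = FALSE] - verts[tris[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nrm <- normalizeRows(nrm)
  eps <- 0.35
  fPlus <- trilinear(field, cent + eps * nrm)
  fMinus <- trilinear(field, cent - eps * nrm)
  flip <- !is.na(fPlus) & !is.na(fMinus) & (fPlus > fMinus)
  tris[flip, c(2, 3)] <- tris[flip, c(3, 2)]
  list(vertices = verts, triangles = tris)
}

# separable [1 2 1]/4 smoothing of a 3D array, zero-padded
smooth121 <- function(a, passes = 2L) {
  for (p in seq_len(passes)) {
    a <- (shiftArray3num(a, 1, 0, 0) + 2 * a + shiftArray3num(a, -1, 0, 0)) / 4
    a <- (shiftArray3num(a, 0, 1, 0) + 2 * a + shiftArray3num(a, 0, -1, 0)) / 4
    a <- (shiftArray3num(a, 0, 0, 1) + 2 * a + shiftArray3num(a, 0, 0, -1)) / 4
  }
  a
}

shiftArray3num <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

# Taubin lambda/mu smoothing of mesh geometry (feature-preserving, low
# shrinkage); connectivity untouched
taubinSmooth <- function(vertices, triangles, iterations = 10L,
                         lambda = 0.5, mu = -0.53) {
  n <- nrow(vertices)
  e <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  for (it in seq_len(iterations)) {
    for (f in c(lambda, mu)) {
      avg <- as.matrix(A %*% vertices) / deg
      vertices <- vertices + f * (avg - vertices)
    }
  }
  vertices
}

#' Extract the WM/GM interface mesh from a segmentation
#'
#' Builds an isosurface of the white-matter indicator: the binary WM mask
#' is lightly smoothed, resampled onto an isotropic grid through the
#' volume affine, and triangulated by a tetrahedral decomposition of the
#' marching-cubes lattice.  The sampling grid spacing is adapted so the
#' mean vertex-to-neighbour distance lands near \code{spacing}.  Output
#' vertices are in world mm; triangle normals point out of the white
#' matter (towards grey matter).
#'
#' @param seg a cleaned [LabelVolume-class] with a WM label.
#' @param spacing target mean edge length in mm (default 0.9).
#' @param smoothIterations Taubin geometry-smoothing iterations applied
#'   to the raw isosurface (default 10).
#' @return a [SurfaceMesh-class], closed per connected component.
#' @export
extractInterfaceMesh <- function(seg, spacing = 0.9, smoothIterations = 10L) {
  if (!"WM" %in% names(seg@labels)) stop("segmentation has no WM label")
  if (abs(det(seg@affine)) < 1e-12) stop("segmentation affine is singular")
  wm <- labelMask(seg, "WM")
  if (!any(wm)) stop("white-matter mask is empty")
  fld <- smooth121(wm * 1.0, passes = 2L)
  idx <- which(wm, arr.ind = TRUE) - 1L
  corners <- as.matrix(expand.grid(range(idx[, 1]) + c(-2, 2),
                                   range(idx[, 2]) + c(-2, 2),
                                   range(idx[, 3]) + c(-2, 2)))
  wcorners <- voxelToWorld(corners, seg@affine)
  lo <- apply(wcorners, 2, min); hi <- apply(wcorners, 2, max)

  h <- spacing / 0.55   # empirical mean-edge / grid-spacing ratio, refined below
  for (attempt in 1:3) {
    nx <- pmax(3L, as.integer(ceiling((hi - lo) / h)) + 1L)
    gx <- lo[1] + h * (0:(nx[1] - 1))
    gy <- lo[2] + h * (0:(nx[2] - 1))
    gz <- lo[3] + h * (0:(nx[3] - 1))
    gridPts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    vox <- worldToVoxel(gridPts, seg@affine)
    vals <- trilinear(fld, vox)
    vals[is.na(vals)] <- 0
    F <- array(vals, dim = nx)
    iso <- marchingTetrahedra(F, 0.5)
    verts <- cbind(lo[1] + h * iso$vertices[, 1],
                   lo[2] + h * iso$vertices[, 2],
                   lo[3] + h * iso$vertices[, 3])
    verts <- taubinSmooth(verts, iso$triangles, iterations = smoothIterations)
    mesh <- SurfaceMesh(verts, iso$triangles)
    me <- meanEdgeLength(mesh)
    if (abs(me - spacing) / spacing <= 0.22 || attempt == 3) return(mesh)
    h <- h * spacing / me
  }
  mesh
}

# ---- decimation ------------------------------------------------------------

#' Decimate a mesh by edge collapse
#'
#' Repeated shortest-edge midpoint collapses with manifold (link
#' condition) and normal-flip guards, until the triangle count reaches
#' \code{ceiling(fraction * nTriangles)}.  Orientation is preserved.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param fraction target triangle fraction in (0, 1]; default 0.5.
#' @return the decimated [SurfaceMesh-class].
#' @export
decimateMesh <- function(mesh, fraction = 0.5) {
  if (fraction <= 0) stop("fraction must be positive")
  if (fraction > 1) stop("fraction must be at most 1")
  if (fraction == 1) return(mesh)
  target <- ceiling(fraction * nTriangles(mesh))
  verts <- mesh@vertices
  tris <- mesh@triangles
  guard <- 0L
  while (nrow(tris) > target && guard < 50L) {
    guard <- guard + 1L
    res <- collapsePass(verts, tris, nrow(tris) - target)
    if (res$collapsed == 0L) break
    verts <- res$vertices; tris <- res$triangles
  }
  keep <- sort(unique(as.vector(tris)))
  remap <- integer(nrow(verts)); remap[keep] <- seq_along(keep)
  SurfaceMesh(verts[keep, , drop = FALSE],
              matrix(remap[tris], ncol = 3))
}

# one greedy pass of independent shortest-edge collapses
collapsePass <- function(verts, tris, maxRemove) {
  n <- nrow(verts)
  e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  len <- rowNorms(verts[e[, 1], , drop = FALSE] - verts[e[, 2], , drop = FALSE])
  ord <- order(len)
  # adjacency sets
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
    adj[[e[k, 2]]] <- c(adj[[e[k, 2]]], e[k, 1])
  }
  vertTris <- vector("list", n)
  for (t in seq_len(nrow(tris)))
    for (v in tris[t, ]) vertTris[[v]] <- c(vertTris[[v]], t)
  locked <- logical(n)
  removedTri <- logical(nrow(tris))
  collapsed <- 0L
  vmap <- seq_len(n)
  for (k in ord) {
    if (collapsed * 2L >= maxRemove) break
    a <- e[k, 1]; b <- e[k, 2]
    if (locked[a] || locked[b]) next
    common <- intersect(adj[[a]], adj[[b]])
    shared <- intersect(vertTris[[a]], vertTris[[b]])
    shared <- shared[!removedTri[shared]]
    if (length(common) != length(shared) || length(shared) == 0L) next
    mid <- (verts[a, ] + verts[b, ]) / 2
    # normal-flip guard on surviving incident triangles
    inc <- setdiff(unique(c(vertTris[[a]], vertTris[[b]])), shared)
    inc <- inc[!removedTri[inc]]
    ok <- TRUE
    for (t in inc) {
      tv <- tris[t, ]
      p0 <- verts[tv, , drop = FALSE]
      tv2 <- ifelse(tv == b, a, tv)
      p1 <- p0
      p1[tv == a | tv == b, ] <- matrix(mid, sum(tv == a | tv == b), 3,
                                        byrow = TRUE)
      n0 <- crossVec(p0[2, ] - p0[1, ], p0[3, ] - p0[1, ])
      n1 <- crossVec(p1[2, ] - p1[1, ], p1[3, ] - p1[1, ])
      if (sum(n0 * n1) <= 0) { ok <- FALSE; break }
    }
    if (!ok) next
    verts[a, ] <- mid
    removedTri[shared] <- TRUE
    vmap[b] <- a
    collapsed <- collapsed + 1L
    locked[c(a, b, adj[[a]], adj[[b]])] <- TRUE
  }
  tris2 <- matrix(vmap[tris], ncol = 3)
  good <- !removedTri & tris2[, 1] != tris2[, 2] &
          tris2[, 2] != tris2[, 3] & tris2[, 1] != tris2[, 3]
  list(vertices = verts, triangles = tris2[good, , drop = FALSE],
       collapsed = collapsed)
}

crossVec <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# ---- offset / transform ----------------------------------------------------

#' Offset a mesh along its vertex normals
#'
#' Displaces every vertex by \code{distance} mm along its outward unit
#' normal (positive = outward expansion, negative = inward shrink).
#' Connectivity is unchanged; self-intersection is permitted and not
#' checked.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param distance signed displacement in mm.
#' @export
offsetMesh <- function(mesh, distance) {
  if (distance == 0) return(mesh)
  SurfaceMesh(mesh@vertices + distance * vertexNormals(mesh),
              mesh@triangles)
}

#' Apply an affine transform to a mesh
#'
#' Vertices are mapped through \code{T}; when the determinant of the
#' linear part is negative the triangle winding is flipped so normals
#' remain outward.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param T 4x4 affine matrix.
#' @export
applyTransform <- function(mesh, T) {
  if (abs(det(T)) < 1e-12) stop("transform is singular")
  v <- cbind(mesh@vertices, 1) %*% t(T)
  tr <- mesh@triangles
  if (det(T[1:3, 1:3]) < 0) tr <- tr[, c(1, 3, 2), drop = FALSE]
  SurfaceMesh(v[, 1:3, drop = FALSE], tr)
}

# ---- Laplace-Beltrami operator --------------------------------------------

#' Cotangent Laplace-Beltrami operator with lumped mass
#'
#' Returns the (positive semi-definite) stiffness matrix L with cotangent
#' weights clamped at zero and the lumped vertex-area mass vector
#' (one third of incident triangle area), both in mm units, suitable for
#' heat diffusion on the surface.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return list with sparse matrix \code{L} and numeric vector \code{mass}.
#' @export
meshLaplacian <- function(mesh) {
  v <- mesh@vertices; tr <- mesh@triangles
  n <- nVertices(mesh)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  corners <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  for (c3 in corners) {
    a <- tr[, c3[1]]; b <- tr[, c3[2]]; cc <- tr[, c3[3]]
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[cc, , drop = FALSE] - v[a, , drop = FALSE]
    cosA <- rowSums(u * w)
    sinA <- rowNorms(cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                           u[, 3] * w[, 1] - u[, 1] * w[, 3],
                           u[, 1] * w[, 2] - u[, 2] * w[, 1]))
    cot <- pmax(cosA / pmax(sinA, 1e-12), 0) / 2  # clamp negatives
    ii <- c(ii, b, cc); jj <- c(jj, cc, b); ww <- c(ww, cot, cot)
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  d <- Matrix::rowSums(W)
  L <- Matrix::Diagonal(x = d) - W
  areas <- triangleAreas(mesh)
  acc <- rowsum(rep(areas / 3, 3), c(tr[, 1], tr[, 2], tr[, 3]))
  massFull <- rep(1e-12, n)
  massFull[as.integer(rownames(acc))] <- as.vector(acc)
  list(L = L, mass = massFull)
}
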