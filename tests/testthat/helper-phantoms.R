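# Shared phantom builders for the test suite.  All are pure functions of
# their arguments; tests that need randomness seed explicitly.

# voxelised ball segmentation: WM sphere of given radius (mm)
ballSegmentation <- function(radius = 20, voxel = 2, n = 30,
                             label = 2L) {
  aff <- diag(c(voxel, voxel, voxel, 1))
  aff[1:3, 4] <- -voxel * (n - 1) / 2
  g <- as.matrix(expand.grid(i = 0:(n - 1), j = 0:(n - 1), k = 0:(n - 1)))
  w <- voxelToWorld(g, aff)
  lab <- array(0L, c(n, n, n))
  lab[sqrt(rowSums(w^2)) <= radius] <- label
  LabelVolume(lab, aff, labels = c(background = 0L, GM = 1L, WM = 2L))
}

# flat triangulated regular grid mesh in the z = 0 plane
flatGridMesh <- function(n = 61, h = 1) {
  gv <- as.matrix(expand.grid(x = 0:(n - 1), y = 0:(n - 1)))
  verts <- cbind(gv * h, 0)
  idx <- function(i, j) (j - 1) * n + i
  i <- rep(1:(n - 1), n - 1)
  j <- rep(1:(n - 1), each = n - 1)
  tris <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  SurfaceMesh(verts, tris)
}

# folded-sheet ("sulcus") mesh: two parallel banks 'gap' mm apart joined
# by a semicircular fundus, extruded along y.  Returns the mesh plus the
# vertex indices at the top of each bank (geodesically far, spatially
# close).
sulcusMesh <- function(depth = 30, gap = 2, length = 40, h = 1) {
  r <- gap / 2
  down <- cbind(-r, seq(depth, 0, by = -h))
  th <- seq(pi, 0, length.out = 8)[-1]
  arc <- cbind(r * cos(th), -r * sin(th))
  up <- cbind(r, seq(h, depth, by = h))
  prof <- rbind(down, arc, up)   # (x, z) profile
  ys <- seq(0, length, by = h)
  np <- nrow(prof); ny <- length(ys)
  verts <- cbind(rep(prof[, 1], ny), rep(ys, each = np),
                 rep(prof[, 2], ny))
  idx <- function(p, q) (q - 1) * np + p
  p <- rep(1:(np - 1), ny - 1)
  q <- rep(1:(ny - 1), each = np - 1)
  tris <- rbind(cbind(idx(p, q), idx(p + 1, q), idx(p + 1, q + 1)),
                cbind(idx(p, q), idx(p + 1, q + 1), idx(p, q + 1)))
  midY <- which.min(abs(ys - length / 2))
  list(mesh = SurfaceMesh(verts, tris),
       bankA = idx(1, midY), bankB = idx(np, midY))
}

# icosahedron subdivided once: every vertex has degree 5 or 6
icosphereMesh <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  # subdivide each triangle into four
  mid <- new.env()
  verts <- v
  getMid <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    if (!is.null(mid[[key]])) return(mid[[key]])
    m <- (verts[a, ] + verts[b, ]) / 2
    m <- m / sqrt(sum(m^2))
    verts <<- rbind(verts, m)
    mid[[key]] <- nrow(verts)
    nrow(verts)
  }
  tris <- NULL
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
    ab <- getMid(a, b); bc <- getMid(b, c); ca <- getMid(c, a)
    tris <- rbind(tris, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                  c(ab, bc, ca))
  }
  SurfaceMesh(verts, tris)
}

# independent brute-force tract dispersion (explicit loops, no shared
# code with the package implementation)
bruteDispersion <- function(trackPts, nPos = 20L) {
  nT <- length(trackPts)
  total <- 0
  dirsAt <- matrix(0, nT, 3)
  for (k in seq_len(nPos)) {
    frac <- (k - 1) / (nPos - 1)
    for (i in seq_len(nT)) {
      p <- trackPts[[i]]
      lens <- numeric(nrow(p) - 1)
      for (s in seq_len(nrow(p) - 1))
        lens[s] <- sqrt(sum((p[s + 1, ] - p[s, ])^2))
      cum <- c(0, cumsum(lens))
      target <- frac * cum[length(cum)]
      seg <- 1L
      while (seg < length(lens) && cum[seg + 1] <= target) seg <- seg + 1L
      d <- p[seg + 1, ] - p[seg, ]
      dirsAt[i, ] <- d / sqrt(sum(d^2))
    }
    mu <- colSums(dirsAt) / nT
    mu <- mu / sqrt(sum(mu^2))
    for (i in seq_len(nT)) {
      cs <- sum(dirsAt[i, ] * mu)
      cs <- max(min(cs, 1), -1)
      total <- total + acos(cs)^2
    }
  }
  total / (nPos * nT)
}

# independent brute-force check that no streamline segment crosses any
# triangle (plain per-pair Moller-Trumbore, scalar loops)
bruteCrossings <- function(trackPts, mesh) {
  v <- meshVertices(mesh); tr <- meshTriangles(mesh)
  hits <- 0L
  for (p in trackPts) {
    for (s in seq_len(nrow(p) - 1)) {
      a <- p[s, ]; dirv <- p[s + 1, ] - p[s, ]
      for (t in seq_len(nrow(tr))) {
        v0 <- v[tr[t, 1], ]; e1 <- v[tr[t, 2], ] - v0; e2 <- v[tr[t, 3], ] - v0
        h <- c(dirv[2] * e2[3] - dirv[3] * e2[2],
               dirv[3] * e2[1] - dirv[1] * e2[3],
               dirv[1] * e2[2] - dirv[2] * e2[1])
        aa <- sum(e1 * h)
        if (abs(aa) < 1e-12) next
        f <- 1 / aa
        sv <- a - v0
        u <- f * sum(sv * h)
        if (u < 0 || u > 1) next
        q <- c(sv[2] * e1[3] - sv[3] * e1[2],
               sv[3] * e1[1] - sv[1] * e1[3],
               sv[1] * e1[2] - sv[2] * e1[1])
        vv <- f * sum(dirv * q)
        if (vv < 0 || u + vv > 1) next
        tt <- f * sum(e2 * q)
        if (tt >= 0 && tt <= 1) hits <- hits + 1L
      }
    }
  }
  hits
}

# empirical FWHM of a smoothed point impulse on a (near-)flat mesh: the
# radius where the radial profile first crosses half of the peak
empiricalFWHM <- function(values, verts, centreIdx) {
  r <- sqrt(rowSums((verts - matrix(verts[centreIdx, ], nrow(verts), 3,
                                    byrow = TRUE))^2))
  half <- max(values) / 2
  rb <- round(r * 2) / 2
  prof <- tapply(values, rb, mean)
  rads <- as.numeric(names(prof))
  i2 <- which(prof < half)[1]
  2 * stats::approx(prof[c(i2 - 1, i2)], rads[c(i2 - 1, i2)],
                    xout = half)$y
}
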