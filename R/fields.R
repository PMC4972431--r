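# Direction fields: a field is a function(pos, prevDir) returning a unit
# 3-vector, or NULL outside its support.  Probabilistic fields draw from
# the R RNG, so results are reproducible under set.seed().

#' Uniform direction field
#'
#' Returns the same unit direction everywhere (sign-aligned to the
#' previous stepping direction).
#'
#' @param v length-3 direction vector.
#' @return a direction-field function.
#' @export
uniformField <- function(v) {
  v <- v / sqrt(sum(v^2))
  function(pos, prevDir = NULL) {
    out <- v
    if (!is.null(prevDir) && sum(out * prevDir) < 0) out <- -out
    out
  }
}

#' Direction field from a vector volume (peak field)
#'
#' Nearest-voxel lookup of a principal-direction volume (for example the
#' leading tensor eigenvector).  Voxels holding the zero vector, and
#' positions outside the grid, are outside the field's support.
#'
#' @param vecs 4D array (x, y, z, 3) of direction vectors.
#' @param affine 4x4 voxel-to-world transform of the grid.
#' @param interpolate trilinearly interpolate the vector components
#'   (renormalised) instead of nearest-voxel lookup; gives a spatially
#'   continuous field, as a minimum-curvature-radius tracker needs
#'   (default FALSE).
#' @return a direction-field function.
#' @export
peakField <- function(vecs, affine, interpolate = FALSE) {
  d <- dim(vecs)
  stopifnot(length(d) == 4L, d[4] == 3L)
  frameLen <- prod(d[1:3])
  if (interpolate) {
    vx <- vecs[, , , 1]; vy <- vecs[, , , 2]; vz <- vecs[, , , 3]
  }
  function(pos, prevDir = NULL) {
    if (interpolate) {
      xyz <- worldToVoxel(pos, affine)
      v <- c(trilinear(vx, xyz), trilinear(vy, xyz), trilinear(vz, xyz))
      if (any(is.na(v))) return(NULL)
    } else {
      ijk <- nearestVoxel(pos, affine)
      if (any(ijk < 0L) || any(ijk >= d[1:3])) return(NULL)
      lin <- 1L + ijk[1] + d[1] * (ijk[2] + d[2] * ijk[3])
      v <- c(vecs[lin], vecs[lin + frameLen], vecs[lin + 2L * frameLen])
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) return(NULL)
    v <- v / nv
    if (!is.null(prevDir) && sum(v * prevDir) < 0) v <- -v
    v
  }
}

#' Curve-following analytic direction field
#'
#' Directions tangent to the nearest of a set of centreline curves
#' (each a nodes x 3 matrix); outside \code{support} mm of every curve
#' the field has no value.  Used by the bundle phantoms.
#'
#' @param curves list of nodes x 3 matrices.
#' @param support max distance (mm) from a centreline (default 6).
#' @return a direction-field function.
#' @export
curveField <- function(curves, support = 6) {
  tangents <- lapply(curves, function(cv) {
    tg <- rbind(diff(cv), cv[nrow(cv), ] - cv[nrow(cv) - 1, ])
    normalizeRows(tg)
  })
  function(pos, prevDir = NULL) {
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_along(curves)) {
      d2 <- rowSums((curves[[i]] -
                     matrix(pos, nrow(curves[[i]]), 3, byrow = TRUE))^2)
      j <- which.min(d2)
      if (d2[j] < best) { best <- d2[j]; bi <- i; bj <- j }
    }
    if (sqrt(best) > support) return(NULL)
    v <- tangents[[bi]][bj, ]
    if (!is.null(prevDir) && sum(v * prevDir) < 0) v <- -v
    v
  }
}

#' Add von Mises-Fisher angular noise to a direction field
#'
#' Each query draws from a vMF distribution centred on the base field's
#' direction with concentration \code{kappa} (larger = tighter).  Uses
#' the R RNG; seed with [set.seed()] for reproducibility.
#'
#' @param baseField a direction-field function.
#' @param kappa vMF concentration parameter.
#' @return a direction-field function.
#' @export
vmfField <- function(baseField, kappa) {
  function(pos, prevDir = NULL) {
    mu <- baseField(pos, prevDir)
    if (is.null(mu)) return(NULL)
    v <- rvmf1(mu, kappa)
    if (!is.null(prevDir) && sum(v * prevDir) < 0) v <- -v
    v
  }
}

# one von Mises-Fisher draw about unit vector mu (Wood's method, p = 3:
# the cosine has an inverse-CDF closed form)
rvmf1 <- function(mu, kappa) {
  u <- stats::runif(1)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  a <- stats::rnorm(3)
  a <- a - sum(a * mu) * mu
  na <- sqrt(sum(a * a))
  if (na < 1e-12) return(mu)
  a <- a / na
  w * mu + sqrt(pmax(1 - w^2, 0)) * a
}
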