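dummySeries <- function(Y, TR = 3, mesh = NULL) {
  if (is.null(mesh))
    mesh <- SurfaceMesh(matrix(seq_len(3 * ncol(Y)), ncol(Y), 3),
                        matrix(c(1, 2, 3), 1))
  new("VertexSeries", data = Y, frameTimes = (seq_len(nrow(Y)) - 1) * TR,
      keptMask = rep(TRUE, nrow(Y)), mesh = mesh)
}

test_that("framewise displacement follows the Power et al. sum", {
  m <- MotionTrace(matrix(0, 5, 3), matrix(0, 5, 3))
  expect_identical(framewiseDisplacement(m), rep(0, 5))
  # one frame translated by 0.5 mm in x: FD 0.5 entering and leaving
  m@translations[3, 1] <- 0.5
  expect_equal(framewiseDisplacement(m), c(0, 0, 0.5, 0.5, 0))
  # a 0.01 rad rotation converts to 0.5 mm arc at 50 mm head radius
  m2 <- MotionTrace(matrix(0, 3, 3), rbind(0, c(0.01, 0, 0), c(0.01, 0, 0)))
  expect_equal(framewiseDisplacement(m2), c(0, 0.5, 0))
  # invariant to adding a constant to any parameter trace
  m3 <- m
  m3@translations <- m@translations + 7
  m3@rotations <- m@rotations + 0.2
  expect_equal(framewiseDisplacement(m3), framewiseDisplacement(m))
  bad <- m; bad@translations[1, 1] <- NA
  expect_error(framewiseDisplacement(bad))
})

test_that("censoring applies the 0.9 mm / 20-frame protocol boundary", {
  out <- censorFrames(rep(0, 180))
  expect_identical(out$status, "ok")
  expect_true(all(out$keptMasks[[1]]))
  # 19 rejections across two scans: masks returned
  fd1 <- rep(0, 90); fd1[1:10] <- 1.0
  fd2 <- rep(0, 90); fd2[1:9] <- 1.0
  out19 <- censorFrames(list(fd1, fd2))
  expect_identical(out19$status, "ok")
  expect_identical(out19$nRejected, 19L)
  expect_identical(sum(!out19$keptMasks[[1]]), 10L)
  # 20 rejections: the dataset itself is rejected
  fd2[10] <- 1.0
  out20 <- censorFrames(list(fd1, fd2))
  expect_identical(out20$status, "rejected")
  expect_null(out20$keptMasks)
  # threshold is strict: FD exactly at 0.9 is kept
  expect_true(all(censorFrames(rep(0.9, 50))$keptMasks[[1]]))
})

test_that("projection samples the nearest EPI voxel 1 mm outside the surface", {
  seg <- ballSegmentation(radius = 20, voxel = 2)
  mesh <- extractInterfaceMesh(seg, spacing = 2)
  d <- c(20L, 20L, 20L, 3L)
  aff <- diag(c(3, 3, 3, 1)); aff[1:3, 4] <- -28.5
  epi <- array(100, d)
  vs <- projectToSurface(epi, aff, mesh, TR = 3)
  expect_true(all(vs@data == 100))
  expect_identical(dim(vs@data), c(3L, nVertices(mesh)))
  # intensity = voxel x index: per-vertex direct-index oracle
  for (f in 1:3) epi[, , , f] <- array(rep(0:(d[1] - 1), prod(d[2:3])), d[1:3])
  vs2 <- projectToSurface(epi, aff, mesh, TR = 3)
  offPts <- meshVertices(offsetMesh(mesh, 1))
  expIdx <- nearestVoxel(offPts, aff)[, 1]
  expect_equal(unname(vs2@data[1, ]), as.numeric(expIdx))
  # a bright 1 mm shell at radius 21 is picked up by the +1 mm offset
  g <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                             k = 0:(d[3] - 1)))
  r <- sqrt(rowSums(voxelToWorld(g, aff)^2))
  shell <- array(0, d[1:3]); shell[r >= 20 & r < 22.5] <- 1000
  epi3 <- array(rep(shell, 3), d)
  vs3 <- projectToSurface(epi3, aff, mesh, TR = 3)
  expect_gt(mean(vs3@data[1, ] == 1000, na.rm = TRUE), 0.6)
  # no vertex inside the volume -> error
  farAff <- aff; farAff[1:3, 4] <- 1000
  expect_error(projectToSurface(epi, farAff, mesh), "no vertex")
})

test_that("surface smoothing preserves constants and the surface integral", {
  seg <- ballSegmentation(radius = 15, voxel = 2, n = 24)
  mesh <- extractInterfaceMesh(seg, spacing = 1.5)
  const <- rep(3.7, nVertices(mesh))
  expect_equal(smoothOnSurface(const, 8, mesh), const, tolerance = 1e-10)
  set.seed(4)
  x <- rnorm(nVertices(mesh))
  sm <- smoothOnSurface(x, 8, mesh)
  mass <- meshLaplacian(mesh)$mass
  expect_equal(sum(mass * sm) / sum(mass * x), 1, tolerance = 1e-9)
  expect_error(smoothOnSurface(x, -1, mesh), "positive")
  # variance strictly shrinks
  expect_lt(stats::var(sm), stats::var(x))
})

test_that("design matrix has the protocol structure", {
  spec <- alternatingBlockDesign()
  ft <- (0:89) * 3
  X <- buildDesign(spec, ft)
  # 270 s scan, 120 s cutoff -> floor(2*270/120) = 4 cosine columns
  expect_identical(sum(grepl("^hpf", colnames(X))), 4L)
  expect_identical(nrow(X), 90L)
  expect_identical(colnames(X)[attr(X, "taskColumn")], "task")
  # nine alternating blocks starting with 'stop': four move plateaus
  task <- X[, "task"]
  high <- task > max(task) / 2
  expect_identical(sum(diff(c(FALSE, high)) == 1L), 4L)
  # censored rows are deleted, not interpolated
  kept <- rep(TRUE, 90); kept[11:13] <- FALSE
  Xc <- buildDesign(spec, ft, kept)
  expect_identical(nrow(Xc), 87L)
  expect_equal(Xc[, "task"], X[kept, "task"])
  # constant-zero covariates are dropped with a warning
  expect_warning(Xz <- buildDesign(spec, ft, rotations = matrix(0, 90, 3)),
                 "constant-zero")
  expect_false(any(grepl("^rot", colnames(Xz))))
  expect_error(buildDesign(spec, ft, rep(FALSE, 90)), "censored")
})

test_that("GLM detects huge effects and flags collinearity", {
  spec <- alternatingBlockDesign()
  ft <- (0:89) * 3
  X <- buildDesign(spec, ft)
  set.seed(11)
  nv <- 50
  Y <- matrix(rnorm(90 * nv), 90, nv) + outer(X[, "task"] * 5, rep(1, nv))
  sm <- fitGLM(dummySeries(Y), X)
  expect_true(all(sm@tstat > 10))
  expect_gt(min(sm@beta), 4)
  Xbad <- cbind(X, dup = X[, "task"])
  attr(Xbad, "taskColumn") <- 1L
  expect_error(fitGLM(dummySeries(Y), Xbad), "rank deficient")
  # contrast invariant to intercept shifts of the data
  sm2 <- fitGLM(dummySeries(Y + 500), X)
  expect_equal(sm2@beta, sm@beta, tolerance = 1e-9)
})

test_that("AR(1) prewhitening recovers the autocorrelation", {
  spec <- alternatingBlockDesign()
  ft <- (0:89) * 3
  X <- buildDesign(spec, ft)
  set.seed(21)
  nv <- 400
  Y <- matrix(0, 90, nv)
  for (v in seq_len(nv))
    Y[, v] <- as.numeric(stats::arima.sim(list(ar = 0.4), 90))
  sm <- fitGLM(dummySeries(Y), X)
  expect_equal(sm@arCoef, 0.4, tolerance = 0.08)
  # whitened residuals are serially uncorrelated beyond the projection
  # bias: compare the pooled lag-1 against its white-noise expectation
  # under the whitened residual-forming matrix
  rho <- sm@arCoef
  W <- function(M) {
    out <- M
    out[1, ] <- sqrt(1 - rho^2) * M[1, ]
    out[-1, ] <- M[-1, , drop = FALSE] - rho * M[-nrow(M), , drop = FALSE]
    out
  }
  Xw <- W(X); Yw <- W(Y)
  E <- Yw - Xw %*% qr.coef(qr(Xw), Yw)
  r1 <- sum(colSums(E[-1, ] * E[-90, ])) / sum(colSums(E^2))
  R <- diag(90) - Xw %*% solve(crossprod(Xw)) %*% t(Xw)
  A <- matrix(0, 90, 90); A[cbind(1:89, 2:90)] <- 0.5; A <- A + t(A)
  r1White <- sum((R %*% A %*% R) * diag(90)) / sum(R * diag(90))
  expect_lt(abs(r1 - r1White), 0.05)
})

test_that("censoring then fitting equals fitting the shorter dataset", {
  spec <- alternatingBlockDesign()
  ft <- (0:89) * 3
  kept <- rep(TRUE, 90); kept[c(10:12, 40, 77)] <- FALSE
  set.seed(31)
  Y <- matrix(rnorm(90 * 30), 90, 30)
  a <- dummySeries(Y); a@keptMask <- kept
  Xa <- buildDesign(spec, ft, kept)
  fitA <- fitGLM(a, Xa)
  b <- new("VertexSeries", data = Y[kept, ], frameTimes = ft[kept],
           keptMask = rep(TRUE, sum(kept)), mesh = a@mesh)
  Xb <- buildDesign(spec, ft[kept])
  fitB <- fitGLM(b, Xb)
  expect_equal(fitA@beta, fitB@beta, tolerance = 1e-12)
  expect_equal(fitA@tstat, fitB@tstat, tolerance = 1e-12)
})

test_that("Bonferroni thresholding keeps exactly the sub-threshold vertices", {
  sm <- new("VertexStatMap", beta = rep(0, 100), tstat = rep(0, 100),
            df = 80, arCoef = 0)
  expect_identical(sum(thresholdFWE(sm)), 0L)
  # one vertex at p = 0.04/n: significant; one at p = 0.06/n: not
  t1 <- qt(1 - 0.04 / 100 / 2, df = 80)
  t2 <- qt(1 - 0.06 / 100 / 2, df = 80)
  sm@tstat[5] <- t1 + 1e-9
  sm@tstat[9] <- t2 - 1e-9
  mask <- thresholdFWE(sm, alpha = 0.05)
  expect_identical(which(mask), 5L)
})

test_that("cluster filtering drops small components and honours selection", {
  mesh <- flatGridMesh(n = 10)
  mask <- rep(FALSE, 100)
  mask[c(1, 2)] <- TRUE                        # 2-vertex component
  mask[c(45, 46, 55, 56, 47)] <- TRUE          # 5-vertex component
  mask[c(91, 92, 93)] <- TRUE                  # 3-vertex component
  out <- filterClusters(mask, mesh)
  expect_identical(sum(out), 8L)               # 2-vertex component dropped
  expect_false(any(out[c(1, 2)]))
  out1 <- filterClusters(mask, mesh, selection = 1L)
  expect_identical(sum(out1), 5L)
  # nearest-point selection (double vector = world point)
  pt <- meshVertices(mesh)[92, ] + 0.1
  outP <- filterClusters(mask, mesh, selection = as.double(pt))
  expect_identical(which(outP), c(91L, 92L, 93L))
  expect_identical(sum(filterClusters(rep(FALSE, 100), mesh)), 0L)
  expect_error(filterClusters(mask, mesh, selection = 5L), "nonexistent")
})

test_that("task masks combine by logical OR", {
  a <- c(TRUE, FALSE, TRUE, FALSE)
  b <- c(FALSE, FALSE, TRUE, TRUE)
  expect_identical(combineTaskMasks(a, b), a | b)
  expect_identical(combineTaskMasks(a, b), combineTaskMasks(b, a))
  expect_identical(combineTaskMasks(a, a), a)
  expect_error(combineTaskMasks(a, b[1:3]), "mismatch")
})
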