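faBox <- function(value = 0.8, n = 40, voxel = 1) {
  aff <- diag(c(voxel, voxel, voxel, 1)); aff[1:3, 4] <- -voxel * n / 2
  list(fa = array(value, c(n, n, n)), affine = aff)
}

test_that("a uniform field gives straight, exactly-spaced streamlines", {
  fb <- faBox()
  pr <- propagate(c(0, 0, -5), c(0, 0, 1), uniformField(c(0, 0, 1)),
                  fb$fa, fb$affine, maxLength = 10)
  expect_identical(nrow(pr$points), 51L)
  expect_identical(pr$reason, "max-length")
  sp <- sqrt(rowSums(diff(pr$points)^2))
  expect_lt(max(abs(sp - 0.2)), 1e-6)
  expect_lt(max(abs(pr$points[, 1:2])), 1e-12)
})

test_that("tracks stop on entering a low-FA voxel, keeping that node", {
  fb <- faBox()
  # slab of FA 0.05 for world z >= 4.5 (voxel centres at z = 5, 6, ...)
  ijk <- which(array(TRUE, dim(fb$fa)), arr.ind = TRUE) - 1L
  wz <- voxelToWorld(ijk, fb$affine)[, 3]
  fa2 <- fb$fa; fa2[wz >= 4.9] <- 0.05
  pr <- propagate(c(0, 0, -5), c(0, 0, 1), uniformField(c(0, 0, 1)),
                  fa2, fb$affine, maxLength = 50)
  expect_identical(pr$reason, "low-fa")
  lastZ <- pr$points[nrow(pr$points), 3]
  # final node is the first node whose nearest voxel lies in the slab
  expect_gte(lastZ, 4.4)
  expect_lt(lastZ, 4.7)
  # FA exactly at the cutoff also terminates (criterion is <= 0.1)
  fa3 <- fb$fa; fa3[wz >= 4.9] <- 0.1
  expect_identical(propagate(c(0, 0, -5), c(0, 0, 1),
                             uniformField(c(0, 0, 1)), fa3, fb$affine,
                             maxLength = 50)$reason, "low-fa")
  expect_error(propagate(c(500, 0, 0), c(0, 0, 1),
                         uniformField(c(0, 0, 1)), fb$fa, fb$affine),
               "outside")
})

test_that("tracks terminate before crossing a constraint triangle", {
  fb <- faBox()
  plane <- SurfaceMesh(rbind(c(-50, -50, 5), c(50, -50, 5), c(50, 50, 5),
                             c(-50, 50, 5)), rbind(c(1, 2, 3), c(1, 3, 4)))
  pr <- propagate(c(0, 0, -5), c(0, 0, 1), uniformField(c(0, 0, 1)),
                  fb$fa, fb$affine, constraint = plane, maxLength = 50)
  expect_identical(pr$reason, "mesh")
  expect_lt(pr$points[nrow(pr$points), 3], 5)
  expect_gt(pr$points[nrow(pr$points), 3], 5 - 0.2 - 1e-9)
  # independent brute-force check: the kept polyline never crosses
  expect_identical(bruteCrossings(list(pr$points), plane), 0L)
})

test_that("the 1 mm curvature radius terminates a 0.5 mm circular field", {
  fb <- faBox()
  circ <- function(pos, prev = NULL) {
    v <- c(-pos[2], pos[1], 0) / sqrt(pos[1]^2 + pos[2]^2 + 1e-12)
    if (!is.null(prev) && sum(v * prev) < 0) v <- -v
    v
  }
  pr <- propagate(c(0.5, 0, 0), c(0, 1, 0), circ, fb$fa, fb$affine,
                  maxLength = 50)
  expect_identical(pr$reason, "curvature")
  expect_lte(nrow(pr$points), 3L)
  # a 2 mm circle is within the allowed curvature
  pr2 <- propagate(c(2, 0, 0), c(0, 1, 0), circ, fb$fa, fb$affine,
                   maxLength = 10)
  expect_identical(pr2$reason, "max-length")
  # discrete turning bound holds with theta_max = 2 asin(0.1)
  d <- diff(pr2$points)
  d <- d / sqrt(rowSums(d^2))
  turns <- acos(pmin(pmax(rowSums(d[-1, ] * d[-nrow(d), ]), -1), 1))
  expect_lte(max(turns), 2 * asin(0.1) + 1e-9)
})

test_that("seeding is area-proportional with uniform barycentric spread", {
  mesh <- SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0),
                            c(10, 0, 0), c(13, 0, 0), c(10, 2, 0)),
                      rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(unname(triangleAreas(mesh)), c(1, 3))
  set.seed(5)
  sd1 <- seedFromSurface(mesh, rep(TRUE, 6), 40000)
  n1 <- sum(sd1$triangle == 1)
  # binomial 3 sigma around 10000 of 40000 at p = 1/4
  expect_lt(abs(n1 - 10000), 3 * sqrt(40000 * 0.25 * 0.75))
  # within one triangle, barycentric coordinates are uniform:
  # Kolmogorov-Smirnov on the first barycentric coordinate, whose
  # marginal CDF under uniform sampling is 1 - (1 - b)^2
  pts <- sd1$points[sd1$triangle == 1, ]
  b1 <- 1 - pts[, 1] - pts[, 2] / 2
  ks <- stats::ks.test(1 - (1 - b1)^2, "punif")
  expect_gt(ks$p.value, 0.01)
  # seeds all inside the triangle; directions are the inward normal
  expect_true(all(pts[, 1] >= -1e-9 & pts[, 2] >= -1e-9))
  expect_equal(unname(sd1$directions[1, ]), c(0, 0, -1))
  expect_error(seedFromSurface(mesh, rep(FALSE, 6), 10), "empty seed")
  # a mask covering no complete triangle is an empty seed region
  expect_error(seedFromSurface(mesh, c(TRUE, TRUE, FALSE, TRUE, FALSE,
                                       TRUE), 10), "empty seed")
})

test_that("ROI pass filter applies the inclusion/exclusion protocol", {
  bd <- makeBundles(seed = 5, nPerBundle = 2)
  rois <- bd$rois
  good <- trackList(bd$tracks)[[1]]              # threads PLIC, ends in stem
  throughCC <- {
    z <- seq(80, 40, by = -0.5)                  # crosses x = 0 at z = 60
    cbind(seq(-20, 20, length.out = length(z)), 0, z)
  }
  endsHigh <- good[1:(nrow(good) - 60), ]        # stops 10+ mm above stem
  neverMid <- cbind(-35, seq(-35, 20, length.out = 100), 50)
  tg <- Tractogram(list(good, throughCC, endsHigh, neverMid,
                        trackList(bd$tracks)[[3]],
                        trackList(bd$tracks)[[5]]))
  out <- roiPassFilter(tg, rois$thalamus, rois$plic, rois$brainstem,
                       rois$cc)
  expect_identical(nTracks(out), 3L)             # the hand-labelled keeps
  # order preserved: kept tracks are 1, 5, 6
  expect_identical(trackList(out)[[1]], good)
})

test_that("generateTracks hits the target, reproduces, and reports failure", {
  bd <- makeBundles(seed = 6, nPerBundle = 2)
  # seed disc above the left corticomotor bundle start, facing down
  disc <- SurfaceMesh(rbind(c(-32, -7, 80), c(-28, -7, 80), c(-30, -3, 80),
                            c(-28, -3, 80)), rbind(c(1, 2, 3), c(2, 4, 3)))
  field <- peakField(bakeFunnelPeaks(bd$centrelines, bd$affine,
                                     dim(bd$fa)), bd$affine,
                     interpolate = TRUE)
  mask <- rep(TRUE, 4)
  res <- generateTracks(disc, mask, field, bd$fa, bd$affine, bd$rois,
                        target = 12, maxAttempts = 600, seed = 9,
                        stopROI = bd$rois$brainstem)
  expect_identical(res$status, "ok")
  expect_identical(res$accepted, 12L)
  expect_identical(nTracks(res$tractogram), 12L)
  res2 <- generateTracks(disc, mask, field, bd$fa, bd$affine, bd$rois,
                         target = 12, maxAttempts = 600, seed = 9,
                         stopROI = bd$rois$brainstem)
  expect_identical(res$tractogram@streamlines, res2$tractogram@streamlines)
  # severed corridor: no track reaches the brainstem
  sev <- makeBundles(seed = 6, nPerBundle = 2, severed = "left")
  resS <- generateTracks(disc, mask, field, sev$fa, sev$affine, sev$rois,
                         target = 5, maxAttempts = 120, seed = 9,
                         stopROI = sev$rois$brainstem)
  expect_identical(resS$status, "no tracks found")
  expect_identical(resS$accepted, 0L)
})
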