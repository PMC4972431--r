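# exhaustive minimum-cost 2-partition over all labelled splits
exhaustiveTwoPartition <- function(F, weights) {
  n <- nrow(F)
  best <- Inf; bestLab <- NULL
  for (code in 1:(2^n - 2)) {
    lab <- as.integer(intToBits(code)[1:n]) + 1L
    if (length(unique(lab)) < 2L) next
    cost <- 0
    for (c in 1:2) {
      sub <- F[lab == c, , drop = FALSE]
      mu <- colMeans(sub)
      d <- sub - matrix(mu, nrow(sub), ncol(F), byrow = TRUE)
      cost <- cost + sum(sweep(d^2, 2, weights[c, ], "*"))
    }
    if (cost < best) { best <- cost; bestLab <- lab }
  }
  list(cost = best, labels = bestLab)
}

stage2Weights <- rbind(rep(1, 12),
                       c(1, 0.49, 1.69, 1.69, 1.69, 1, 1, 1, 1, 1, 1, 1))

test_that("stage-1 features read off cortex and midbrain-entry coordinates", {
  bd <- makeBundles(seed = 3, nPerBundle = 2)
  rois <- bd$rois
  z <- seq(80, 0, by = -0.2)
  straight <- cbind(rep(12, length(z)),
                    seq(2, -6, length.out = length(z)), z)
  f <- stage1Features(straight, rois$thalamus, rois$plic)
  expect_identical(f[1:2], c(12, 2))
  entry <- straight[firstNodeInROI(straight, rois$plic), ]
  expect_equal(f[3:4], unname(entry[1:2]))
  # thalamus entry counts the same as PLIC entry
  tcLike <- cbind(rep(8, length(z)),
                  seq(-10, -14, length.out = length(z)), z)
  fT <- stage1Features(tcLike, rois$thalamus, rois$plic)
  expect_equal(fT[3:4],
               unname(tcLike[firstNodeInROI(tcLike, rois$thalamus), 1:2]))
  # mirror symmetry
  mir <- straight; mir[, 1] <- -mir[, 1]
  fM <- stage1Features(mir, rois$thalamus, rois$plic)
  expect_equal(fM, f * c(-1, 1, -1, 1))
  # never entering either ROI is an error
  outside <- cbind(rep(-39, 50), rep(-39, 50), seq(80, 0, length.out = 50))
  expect_error(stage1Features(outside, rois$thalamus, rois$plic),
               "never enters")
})

test_that("stage-2 features are direct reads with index clamping", {
  bd <- makeBundles(seed = 3, nPerBundle = 2)
  rois <- bd$rois
  z <- seq(80, 0, by = -0.2)                     # 401 nodes
  trk <- cbind(rep(12, length(z)), seq(6, -2, length.out = length(z)), z)
  f <- stage2Features(trk, rois$thalamus, rois$plic, rois$brainstem)
  m <- firstNodeInROI(trk, rois$plic)
  expect_equal(f[1:2], unname(trk[m, 1:2]))
  expect_equal(f[3:5], unname(trk[m + 50, ]))
  expect_equal(f[6:8], unname(trk[nrow(trk) - 50, ]))
  expect_equal(f[9:10], unname(trk[nrow(trk), 1:2]))
  expect_identical(unname(f[11]), 1)             # passes PLIC
  expect_identical(unname(f[12]), 0)             # not thalamus
  expect_false(attr(f, "clamped"))
  # a track traversing both midbrain ROIs on the slice flags both
  both <- rbind(cbind(10, -2, seq(80, 40.5, by = -0.4)),
                cbind(10, seq(-2, -12, by = -0.4), 40.5),
                cbind(10, -12, seq(40.5, 0, by = -0.4)))
  fB <- stage2Features(both, rois$thalamus, rois$plic, rois$brainstem)
  expect_identical(unname(fB[11:12]), c(1, 1))
  # short track: indices clamp to the terminal node and are flagged
  short <- trk[seq(m - 10, m + 30), ]
  fS <- stage2Features(short, rois$thalamus, rois$plic, rois$brainstem)
  expect_equal(fS[3:5], unname(short[nrow(short), ]))
  expect_true(attr(fS, "clamped"))
})

test_that("weighted k-means matches closed forms and exhaustive optima", {
  set.seed(17)
  # k = 1: centroid and total weighted variance
  F <- matrix(rnorm(40), 10, 4)
  w <- matrix(c(2, 1, 0.5, 3), 1)
  r1 <- weightedKMeans(F, 1, weights = w)
  expect_equal(r1@centers[1, ], colMeans(F))
  expect_equal(r1@cost,
               sum(sweep(sweep(F, 2, colMeans(F))^2, 2, w[1, ], "*")))
  # weight 0 on a feature equals dropping the feature
  F2 <- cbind(F, noise = rnorm(10) * 100)
  w2 <- rbind(c(1, 1, 1, 1, 0), c(1, 1, 1, 1, 0))
  set.seed(1); rA <- weightedKMeans(F2, 2, weights = w2, attempts = 10)
  set.seed(1); rB <- weightedKMeans(F, 2, attempts = 10)
  expect_identical(rA@labels, rB@labels)
  expect_equal(rA@cost, rB@cost)
  # two well-separated clouds: exhaustive oracle agreement
  for (rep in 1:10) {
    n <- sample(5:11, 1)
    G <- matrix(rnorm(n * 4), n, 4) +
      2.5 * (sample(0:1, n, replace = TRUE))
    km <- weightedKMeans(G, 2, attempts = 25)
    ex <- exhaustiveTwoPartition(G, matrix(1, 2, 4))
    expect_equal(km@cost, ex$cost, tolerance = 1e-9)
  }
  expect_error(weightedKMeans(F, 20), "exceeds")
  # reported cost equals independent recomputation from the labels
  km <- weightedKMeans(F, 3, attempts = 5)
  recomputed <- 0
  for (c in 1:3) {
    sel <- km@labels == c
    mu <- colMeans(F[sel, , drop = FALSE])
    recomputed <- recomputed +
      sum(sweep(F[sel, , drop = FALSE], 2, mu)^2)
  }
  expect_equal(km@cost, recomputed, tolerance = 1e-9)
})

test_that("k-means solutions are locally optimal under single relabels", {
  set.seed(23)
  F <- matrix(rnorm(15 * 12), 15, 12) + 2 * (rep(0:1, c(8, 7)))
  km <- weightedKMeans(F, 2, weights = stage2Weights, attempts = 20)
  for (i in 1:15) {
    lab2 <- km@labels
    lab2[i] <- 3L - lab2[i]
    if (length(unique(lab2)) < 2L) next
    cost2 <- 0
    for (c in 1:2) {
      sub <- F[lab2 == c, , drop = FALSE]
      mu <- colMeans(sub)
      cost2 <- cost2 + sum(sweep(sweep(sub, 2, mu)^2, 2,
                                 stage2Weights[c, ], "*"))
    }
    expect_gte(cost2, km@cost - 1e-9)
  }
})

test_that("hemisphere split separates mirrored bundles exactly", {
  bd <- makeBundles(seed = 8, nPerBundle = 10)
  set.seed(2)
  sp <- splitHemispheres(bd$tracks, bd$rois$thalamus, bd$rois$plic)
  md <- trackMetadata(bd$tracks)
  expect_identical(nTracks(sp$left), sum(md$hemisphere == "left"))
  expect_true(all(trackMetadata(sp$left)$hemisphere == "left"))
  expect_true(all(trackMetadata(sp$right)$hemisphere == "right"))
  # single-hemisphere input: one empty output, not an error
  leftOnly <- subsetTracks(bd$tracks, md$hemisphere == "left")
  spL <- splitHemispheres(leftOnly, bd$rois$thalamus, bd$rois$plic)
  expect_identical(nTracks(spL$right), 0L)
  expect_identical(nTracks(spL$left), nTracks(leftOnly))
  # determinism under a fixed seed
  set.seed(77); a <- splitHemispheres(bd$tracks, bd$rois$thalamus, bd$rois$plic)
  set.seed(77); b <- splitHemispheres(bd$tracks, bd$rois$thalamus, bd$rois$plic)
  expect_identical(a$left@streamlines, b$left@streamlines)
  expect_error(splitHemispheres(subsetTracks(bd$tracks, 1),
                                bd$rois$thalamus, bd$rois$plic), "two")
})

test_that("corticomotor/thalamocortical classification recovers truth", {
  bd <- makeBundles(seed = 14)
  set.seed(3)
  sp <- splitHemispheres(bd$tracks, bd$rois$thalamus, bd$rois$plic)
  cr <- classifyMotorThalamic(sp$right, bd$rois$thalamus, bd$rois$plic,
                              bd$rois$brainstem, bd$brainCentre)
  truth <- ifelse(trackMetadata(sp$right)$class == "thalamocortical",
                  1L, 2L)
  expect_gte(mean(cr@labels == truth), 0.95)
  expect_identical(attr(cr, "labelNames"),
                   c("thalamocortical", "corticomotor"))
  # reported cost equals recomputation under the per-cluster weights
  F <- t(vapply(sp$right@streamlines, function(p)
    as.numeric(stage2Features(p, bd$rois$thalamus, bd$rois$plic)),
    numeric(12)))
  rec <- 0
  for (c in 1:2) {
    sub <- F[cr@labels == c, , drop = FALSE]
    mu <- colMeans(sub)
    rec <- rec + sum(sweep(sweep(sub, 2, mu)^2, 2, stage2Weights[c, ], "*"))
  }
  expect_equal(cr@cost, rec, tolerance = 1e-9)
})

test_that("ten-track classification attains the exhaustive optimum", {
  bd <- makeBundles(seed = 9, nPerBundle = 5)
  set.seed(4)
  sp <- splitHemispheres(bd$tracks, bd$rois$thalamus, bd$rois$plic)
  cr <- classifyMotorThalamic(sp$left, bd$rois$thalamus, bd$rois$plic,
                              bd$rois$brainstem, bd$brainCentre)
  F <- t(vapply(sp$left@streamlines, function(p)
    as.numeric(stage2Features(p, bd$rois$thalamus, bd$rois$plic)),
    numeric(12)))
  ex <- exhaustiveTwoPartition(F, stage2Weights)
  expect_equal(cr@cost, ex$cost, tolerance = 1e-9)
})

test_that("pyramid fallback initialisation still classifies", {
  # construct tracks none of which touch the anterior third of the
  # brainstem ROI: all final nodes posterior
  bd <- makeBundles(seed = 10, nPerBundle = 2)
  z <- seq(80, 0, by = -0.2)
  mk <- function(x0, y0, yEnd) cbind(
    seq(x0, 5, length.out = length(z)),
    seq(y0, yEnd, length.out = length(z)), z)
  tg <- Tractogram(list(mk(25, -2, -9), mk(26, -3, -10),
                        mk(18, -16, -11), mk(20, -17, -12)))
  set.seed(5)
  expect_silent(cr <- classifyMotorThalamic(tg, bd$rois$thalamus,
                                            bd$rois$plic,
                                            bd$rois$brainstem,
                                            bd$brainCentre))
  expect_identical(sort(unique(cr@labels)), c(1L, 2L))
  # fewer than two tracks: single-cluster result with a warning
  expect_warning(one <- classifyMotorThalamic(subsetTracks(tg, 1),
                                              bd$rois$thalamus,
                                              bd$rois$plic,
                                              bd$rois$brainstem,
                                              bd$brainCentre),
                 "fewer than two")
  expect_identical(length(one@labels), 1L)
})

test_that("classification is invariant to track order up to relabelling", {
  bd <- makeBundles(seed = 12, nPerBundle = 8)
  set.seed(6)
  sp <- splitHemispheres(bd$tracks, bd$rois$thalamus, bd$rois$plic)
  hemi <- sp$left
  set.seed(101)
  a <- classifyMotorThalamic(hemi, bd$rois$thalamus, bd$rois$plic,
                             bd$rois$brainstem, bd$brainCentre)
  perm <- sample(nTracks(hemi))
  set.seed(102)
  b <- classifyMotorThalamic(subsetTracks(hemi, perm), bd$rois$thalamus,
                             bd$rois$plic, bd$rois$brainstem,
                             bd$brainCentre)
  expect_identical(a@labels[perm], b@labels)
  expect_equal(a@cost, b@cost, tolerance = 1e-9)
})
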