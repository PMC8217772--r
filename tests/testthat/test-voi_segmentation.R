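# Thresholding, contour matching and the two VOI segmentation procedures.

test_that("caudal-third removal zeroes the right slices", {
  img <- VolumeImage(array(1, c(4, 4, 159)), c(1, 1, 1))
  out <- dropCaudalThird(img)
  expect_true(all(out@voxels[, , 107:159] == 0))  # last 53 slices
  expect_true(all(out@voxels[, , 1:106] == 1))
  img3 <- VolumeImage(array(1, c(3, 3, 3)), c(1, 1, 1))
  expect_true(all(dropCaudalThird(img3)@voxels[, , 3] == 0))
  z <- VolumeImage(array(0, c(3, 3, 6)), c(1, 1, 1))
  expect_equal(dropCaudalThird(z)@voxels, z@voxels)
})

test_that("Otsu threshold maximises between-class variance (brute force)", {
  set.seed(10)
  v <- c(rnorm(100, 1, 0.1), rnorm(100, 10, 0.5))
  t1 <- otsuThresholds(v, 1)
  expect_true(t1 > max(v[v < 5]) && t1 < min(v[v > 5]))
  # two-valued input: threshold strictly separates a and b
  t2 <- otsuThresholds(c(rep(2, 6), rep(9, 4)), 1)
  expect_true(t2 > 2 && t2 <= 9)
  expect_error(otsuThresholds(rep(1, 10)), "distinct")
  # brute-force oracle on an arbitrary histogram: maximise between-class
  # variance over all 256-bin cut points (same plateau tie rule: middle)
  set.seed(11)
  x <- c(rgamma(300, 2, 1), rnorm(150, 8, 1))
  nb <- 256L
  br <- seq(min(x), max(x), length.out = nb + 1)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), nb),
                nbins = nb)
  mid <- (br[-1] + br[-length(br)]) / 2
  wTot <- sum(h); muTot <- sum(h * mid) / wTot
  bcv <- vapply(seq_len(nb - 1), function(j) {
    w0 <- sum(h[1:j]); w1 <- wTot - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    m0 <- sum(h[1:j] * mid[1:j]) / w0
    m1 <- (sum(h * mid) - w0 * m0) / w1
    w0 * (m0 - muTot)^2 + w1 * (m1 - muTot)^2
  }, numeric(1))
  opt <- which(bcv >= max(bcv) - 1e-9)
  cut <- opt[ceiling(length(opt) / 2)]
  expect_equal(otsuThresholds(x, 1), br[cut + 1], tolerance = 1e-9)
})

test_that("adaptive volume threshold homes in on the target object size", {
  # nested-intensity sphere: core 10, shell 5, background 0
  core <- ellipsoidMask(32, c(6, 6, 6))
  shell <- ellipsoidMask(32, c(11, 11, 11)) & !core
  v <- array(0, c(32, 32, 32)); v[shell] <- 5; v[core] <- 10
  img <- VolumeImage(v, c(1, 1, 1))
  res <- adaptiveVolumeThreshold(img, sum(core))
  expect_true(res$threshold > 5 && res$threshold <= 10)
  expect_equal(sum(res$mask@voxels & core), sum(res$mask@voxels))
  # two blobs: largest-component rule
  b1 <- ellipsoidMask(40, c(8, 8, 8), center = c(14, 14, 14))
  b2 <- ellipsoidMask(40, c(4, 4, 4), center = c(30, 30, 30))
  v2 <- array(0, c(40, 40, 40)); v2[b1 | b2] <- 7
  res2 <- adaptiveVolumeThreshold(VolumeImage(v2, c(1, 1, 1)), sum(b1))
  expect_true(all(res2$mask@voxels[b2] == FALSE))
  expect_gt(diceCoef(res2$mask@voxels, b1), 0.99)
  # nothing near the target size: segmentation failure
  expect_error(adaptiveVolumeThreshold(VolumeImage(v2, c(1, 1, 1)),
                                       sum(b1) * 10),
               "segmentation failure")
})

test_that("boundary-F1 agrees with an all-pairs distance oracle", {
  m <- ellipsoidMask(20, c(5, 5, 5))
  expect_equal(bfScore(m, m), 1)
  far1 <- array(FALSE, c(24, 24, 24)); far1[2:5, 2:5, 2:5] <- TRUE
  far2 <- array(FALSE, c(24, 24, 24)); far2[18:22, 18:22, 18:22] <- TRUE
  expect_equal(bfScore(far1, far2), 0)
  expect_error(bfScore(far1, m), "shapes")
  # cube vs cube shifted by one voxel at several tolerances: oracle computes
  # all-pairs nearest boundary distances directly
  a <- array(FALSE, c(14, 14, 14)); a[4:9, 4:9, 4:9] <- TRUE
  b <- array(FALSE, c(14, 14, 14)); b[5:10, 4:9, 4:9] <- TRUE
  oracleBf <- function(a, b, tol) {
    bnd <- function(m) {
      keep <- array(FALSE, dim(m))
      idx <- which(m, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        p <- idx[r, ]
        for (k in 1:3) for (s in c(-1, 1)) {
          q <- p; q[k] <- q[k] + s
          if (any(q < 1) || any(q > dim(m)) || !m[q[1], q[2], q[3]]) {
            keep[p[1], p[2], p[3]] <- TRUE
          }
        }
      }
      which(keep, arr.ind = TRUE)
    }
    A <- bnd(a); B <- bnd(b)
    dmat <- as.matrix(stats::dist(rbind(A, B)))
    cross <- dmat[seq_len(nrow(A)), nrow(A) + seq_len(nrow(B)), drop = FALSE]
    pr <- mean(apply(cross, 1, min) <= tol)
    rc <- mean(apply(cross, 2, min) <= tol)
    if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  }
  for (tol in c(1, 1.5, 2)) {
    expect_equal(bfScore(a, b, tol), oracleBf(a, b, tol), tolerance = 1e-12)
  }
  expect_equal(bfScore(a, b, 1), bfScore(b, a, 1))  # symmetry
})

test_that("rotation search recovers an applied rotation and honours ties", {
  ph <- ellipsoidMask(64, c(26, 12, 20))
  # identity: candidate equals the atlas mask
  rs0 <- rotationSearch(ph, ph)
  expect_equal(rs0$bestRotation, c(0, 0, 0))
  expect_equal(rs0$bestScore, 1)
  # +10 degrees about z recovered within one 2-degree grid step
  cand <- moveArray(ph, c(0, 0, 10), linear = FALSE) > 0.5
  dim(cand) <- dim(ph)
  rs <- rotationSearch(cand, ph)
  expect_lte(abs(rs$bestRotation[3] - 10), 2)
  expect_gt(rs$bestScore, 0.9)
  # rotation-invariant sphere: tie-break returns zero rotation
  sp <- ellipsoidMask(28, c(8, 8, 8))
  rsS <- rotationSearch(sp, sp)
  expect_equal(rsS$bestRotation, c(0, 0, 0))
  expect_error(rotationSearch(sp, array(FALSE, dim(sp))), "empty")
})

test_that("metabolic VOI segmentation reaches Dice >= 0.9 on the phantom", {
  spec <- phantomSpec(seed = 21)
  ph <- makeAtlasPhantom(spec)
  sf <- computeScaleFactor(spec$petSpacing[1], ph$atlas@spacing[1])
  fa <- resizeSubregions(ph$atlas, sf)
  co <- makePetCohort(spec, nAnimals = 1, states = "healthy")
  pp <- preprocessImage(co$images[[1]][[1]])
  sm <- sumFrames(pp$image)
  amask <- BinaryMask(petquant:::padCropTo(fa@brainMask@voxels,
                                           dim(sm@voxels)), sm@spacing)
  seg <- segmentVoiMetabolic(sm, amask)
  gt <- co$groundTruth[[1]]
  truth <- moveArray(co$groundTruth$.brainMask, gt$angles_deg,
                     gt$translation_vox) > 0.5
  dim(truth) <- spec$petDim
  truth <- truth[, , 6:75]
  expect_gte(diceCoef(seg@voiMask@voxels, truth), 0.9)
  # single connected component inside the thresholded candidate
  lab <- petquant:::cpp_cc_label(seg@voiMask@voxels, 26L)
  expect_equal(max(lab), 1L)
  # already axis-aligned, centred phantom with uniform uptake (so the
  # adaptive threshold keeps the whole brain): zero rotation
  specU <- phantomSpec(seed = 21,
                       regionMeans = c(olfactory = 5, cortex = 5,
                                       thalamus = 5, hippocampus = 5,
                                       cerebellum = 5))
  tp <- petquant:::tracerPattern(specU)$pattern
  segA <- segmentVoiMetabolic(VolumeImage(tp, specU$petSpacing),
                              BinaryMask(petquant:::petGridLabels(specU) > 0,
                                         specU$petSpacing))
  expect_equal(segA@bestRotation, c(0, 0, 0))
  # no structure near the atlas size: error
  flat <- VolumeImage(array(c(0, 1)[1 + (ellipsoidMask(48, c(3, 3, 3)))],
                            c(48, 48, 48)), c(1, 1, 1))
  expect_error(segmentVoiMetabolic(flat,
                                   BinaryMask(ellipsoidMask(48, c(15, 12, 18)),
                                              c(1, 1, 1))),
               "segmentation failure")
})

test_that("target-selective VOI segmentation reaches Dice >= 0.8", {
  spec <- phantomSpec(tracerMode = "target_selective", seed = 22)
  ph <- makeAtlasPhantom(spec)
  sf <- computeScaleFactor(spec$petSpacing[1], ph$atlas@spacing[1])
  fa <- resizeSubregions(ph$atlas, sf)
  co <- makePetCohort(spec, nAnimals = 1, states = "stroke")
  pp <- preprocessImage(co$images[[1]][[1]])
  sm <- sumFrames(pp$image)
  amask <- BinaryMask(petquant:::padCropTo(fa@brainMask@voxels,
                                           dim(sm@voxels)), sm@spacing)
  seg <- segmentVoiTargetSelective(sm, amask)
  gt <- co$groundTruth[[1]]
  truth <- moveArray(co$groundTruth$.brainMask, gt$angles_deg,
                     gt$translation_vox) > 0.5
  dim(truth) <- spec$petDim
  expect_gte(diceCoef(seg@voiMask@voxels, truth[, , 6:75]), 0.8)
  expect_error(segmentVoiTargetSelective(
    VolumeImage(array(0, c(24, 24, 24)), c(1, 1, 1)),
    BinaryMask(ellipsoidMask(24, c(6, 5, 7)), c(1, 1, 1))), "empty image")
})
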