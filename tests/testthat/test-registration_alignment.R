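# Known-transform recovery, transform reuse, auxiliary structures and
# similarity measures.

test_that("rigid registration recovers identity, translation and rotation", {
  fix <- blobImage(40)
  # identity
  tr0 <- rigidRegister(fix, fix)
  expect_lt(max(abs(tr0@parameters$angles_deg)), 0.1)
  expect_lt(max(abs(tr0@parameters$translation_vox)), 0.1)
  # translation (3, -2, 1) voxels: the estimated correction is its negative
  mv <- VolumeImage(moveArray(fix@voxels, trans = c(3, -2, 1)), fix@spacing)
  tr <- rigidRegister(mv, fix)
  expect_lt(max(abs(tr@parameters$translation_vox + c(3, -2, 1))), 0.5)
  # rotation 8 degrees about z
  mv2 <- VolumeImage(moveArray(fix@voxels, angles = c(0, 0, 8)), fix@spacing)
  tr2 <- rigidRegister(mv2, fix)
  expect_lt(abs(tr2@parameters$angles_deg[3] + 8), 1)
  # resampling with the transform aligns the data
  res <- applyTransform(mv2, tr2)
  expect_lt(sqrt(mean((res@voxels - fix@voxels)^2)),
            0.02 * max(fix@voxels))
  # rigid transforms keep an orthonormal, det +1 linear part
  expect_lt(max(abs(crossprod(tr2@parameters$A) - diag(3))), 1e-6)
})

test_that("affine registration recovers a known scale and a cross-modality shift", {
  fix <- blobImage(40)
  d <- dim(fix@voxels); ctr <- (d - 1) / 2
  A <- diag(3) * 1.1
  mvArr <- petquant:::cpp_resample_affine(fix@voxels, as.integer(d), A,
                                          as.numeric(ctr - A %*% ctr), TRUE)
  mv <- VolumeImage(mvArr, fix@spacing)
  tr <- affineRegister(mv, fix, metric = "correlation")
  expect_lt(max(abs(exp(tr@parameters$log_scale) - 1.1)), 0.022)
  # cross-modality: intensity remap plus a shift, mutual-information metric
  remap <- VolumeImage(max(fix@voxels) - fix@voxels^0.7, fix@spacing)
  mvx <- VolumeImage(moveArray(remap@voxels, trans = c(2, -1, 1)),
                     fix@spacing)
  trx <- affineRegister(mvx, fix, metric = "mutual_information")
  expect_lt(max(abs(trx@parameters$translation_vox + c(2, -1, 1))), 1)
})

test_that("transform application composes chains in one pass", {
  img <- blobImage(32)
  # empty chain is the identity
  expect_equal(applyTransform(img, list())@voxels, img@voxels)
  # integral translation is an exact voxel shift
  shift <- new("Transform", kind = "rigid",
               parameters = list(A = diag(3), b = c(2, 0, 0)),
               fixedFrame = "b", movingFrame = "a")
  out <- applyTransform(img, shift)
  expect_equal(out@voxels[1:30, , ], img@voxels[3:32, , ], tolerance = 1e-12)
  # T then T^-1 round trip
  tr <- new("Transform", kind = "affine",
            parameters = list(A = petquant:::rotationMatrix3(c(0, 0, 5)),
                              b = c(1.3, -0.7, 0.4)),
            fixedFrame = "b", movingFrame = "a")
  inv <- invertTransform(tr)
  chain <- new("TransformChain",
               transforms = list(tr,
                                 new("Transform", kind = inv@kind,
                                     parameters = inv@parameters,
                                     fixedFrame = "c", movingFrame = "b")))
  rt <- applyTransform(img, chain)
  core <- 6:27 # interior, away from resampling borders
  rms <- sqrt(mean((rt@voxels[core, core, core] -
                    img@voxels[core, core, core])^2))
  expect_lt(rms, 0.01 * diff(range(img@voxels)))
  # dynamic images: identical spatial transform for every frame
  dyn <- DynamicImage(array(rep(img@voxels, 2), c(dim(img@voxels), 2)),
                      img@spacing, frameTable(c(0, 600), c(600, 1200)))
  dout <- applyTransform(dyn, shift)
  expect_identical(dout@voxels[, , , 1], dout@voxels[, , , 2])
})

test_that("auxiliary structures keep the VOI plus linked high-uptake regions", {
  spec <- phantomSpec(seed = 33)
  tp <- petquant:::tracerPattern(spec)
  img <- VolumeImage(tp$pattern, spec$petSpacing)
  aux <- buildAuxMetabolic(img, tp$brainMask)
  # both hotspots and the brain survive
  hot <- tp$pattern > 1.4 * max(spec$regionMeans) * 1000
  expect_true(sum(aux@voxels[hot] > 0) / sum(hot) > 0.9)
  inBrain <- aux@voxels > 0 & tp$brainMask
  expect_gt(sum(inBrain) / sum(tp$brainMask), 0.8)
  expect_error(buildAuxMetabolic(VolumeImage(array(0, c(8, 8, 8)),
                                             c(1, 1, 1)),
                                 array(TRUE, c(8, 8, 8))), "empty")
  # target-selective auxiliary: head contribution at most half the original
  spec2 <- phantomSpec(tracerMode = "target_selective", seed = 34)
  tp2 <- petquant:::tracerPattern(spec2)
  img2 <- VolumeImage(tp2$pattern, spec2$petSpacing)
  voi2 <- BinaryMask(tp2$brainMask, spec2$petSpacing)
  aux2 <- buildAuxTarget(img2, voi2)
  headRegion <- tp2$pattern > 0 & !petquant:::morph3(tp2$brainMask, "dilate")
  expect_lte(max(aux2@voxels[headRegion]), 0.5 * max(img2@voxels[headRegion]))
  # inversion: brightest VOI output lies in formerly dimmest brain tissue
  brainOnly <- tp2$brainMask & tp2$pattern <= 1000
  expect_gte(max(aux2@voxels[brainOnly]),
             max(aux2@voxels[tp2$brainMask & tp2$pattern > 1000]))
  # VOI covering everything: warning path
  expect_warning(buildAuxTarget(img2, BinaryMask(array(TRUE, dim(tp2$pattern)),
                                                 spec2$petSpacing)),
                 "head mask empty")
})

test_that("subject-state alignment recovers a known within-subject offset", {
  spec <- phantomSpec(seed = 35, noiseSigma = 0, maxRotationDeg = 0,
                      maxTranslationVox = 0, petDim = c(48L, 48L, 60L),
                      brainSemiAxes = c(10, 8, 12),
                      nFrames = 2L)
  co <- makePetCohort(spec, nAnimals = 1, states = "healthy")
  ctrl <- co$images[[1]][["healthy"]]
  moved <- ctrl
  for (f in seq_len(nFrames(ctrl)))
    moved@voxels[, , , f] <- moveArray(ctrl@voxels[, , , f],
                                       trans = c(3, 1, -2))
  series <- list(Rat_No_1 = list(healthy = ctrl, stroke = moved))
  al <- alignSubjectStates(series)
  tr <- al$chains$Rat_No_1$stroke@transforms[[1]]
  expect_lt(max(abs(tr@parameters$translation_vox + c(3, 1, -2))), 0.5)
  # control chain is empty (no-op), disease states fan in on the control
  expect_length(al$chains$Rat_No_1$healthy@transforms, 0L)
  rms <- sqrt(mean((sumFrames(al$aligned$Rat_No_1$stroke)@voxels -
                    sumFrames(ctrl)@voxels)^2))
  expect_lt(rms, 0.05 * max(sumFrames(ctrl)@voxels))
})

test_that("template alignment improves similarity and reuses control chains", {
  img <- blobImage(32)
  m <- BinaryMask(img@voxels > 0.3, img@spacing)
  tmpl <- buildTemplate(list(img), list(m), 1L)
  mkDyn <- function(v) DynamicImage(array(v, c(dim(v), 1)), img@spacing,
                                    frameTable(0, 600))
  mv <- moveArray(img@voxels, c(0, 0, 4), c(1.5, -1, 0))
  subjects <- list(
    aligned = list(s1 = list(healthy = mkDyn(mv), stroke = mkDyn(mv))),
    chains = list(s1 = list(
      healthy = new("TransformChain", transforms = list()),
      stroke = new("TransformChain", transforms = list()))))
  out <- alignToTemplate(subjects, tmpl, iterations = 80L)
  before <- similarityReport(sumFrames(subjects$aligned$s1$healthy),
                             tmpl@image)$pearson
  after <- similarityReport(sumFrames(out$aligned$s1$healthy),
                            tmpl@image)$pearson
  expect_gt(after, before)
  # reuse: stroke (same voxels as control here) gets bitwise the same result
  expect_identical(out$aligned$s1$stroke@voxels[, , , 1],
                   out$aligned$s1$healthy@voxels[, , , 1])
})

test_that("similarity report matches information-theoretic identities", {
  img <- blobImage(24)
  s <- similarityReport(img, img)
  expect_equal(s$pearson, 1)
  expect_equal(s$spearman, 1)
  # MI(a, a) equals H(a) under the same binning
  expect_equal(s$mutual_information, s$joint_entropy, tolerance = 1e-9)
  neg <- VolumeImage(-img@voxels, img@spacing)
  s2 <- similarityReport(img, neg)
  expect_equal(s2$pearson, -1)
  expect_equal(s2$spearman, -1)
  # independent noise: MI below the finite-sample bias bound
  set.seed(99)
  n <- 100L
  a <- VolumeImage(array(runif(n^3), c(n, n, n)), c(1, 1, 1))
  b <- VolumeImage(array(runif(n^3), c(n, n, n)), c(1, 1, 1))
  s3 <- similarityReport(a, b)
  expect_lt(s3$mutual_information, 0.01)
  # constant image: flagged degenerate
  cst <- VolumeImage(array(2, c(8, 8, 8)), c(1, 1, 1))
  s4 <- similarityReport(cst, img <- VolumeImage(array(runif(512),
                                                       c(8, 8, 8)),
                                                 c(1, 1, 1)))
  expect_true(s4$degenerate)
  expect_true(is.na(s4$pearson))
})

test_that("second-template members are never deformably registered", {
  spec <- phantomSpec(seed = 36, petDim = c(48L, 48L, 60L),
                      brainSemiAxes = c(10, 8, 12), nFrames = 2L,
                      maxRotationDeg = 3, maxTranslationVox = 1.5)
  co <- makePetCohort(spec, nAnimals = 2, states = "stroke")
  summed <- lapply(co$images, function(s) sumFrames(preprocessImage(s[[1]])$image))
  names(summed) <- names(co$images)
  amask <- petquant:::padCropTo(petquant:::petGridLabels(spec) > 0,
                                dim(summed[[1]]@voxels))
  masks <- lapply(summed, function(s) segmentVoiMetabolic(s, amask)@voiMask)
  tmplP <- buildTemplate(summed, unname(masks), 1L, iterations = 40L)
  st2 <- secondTemplateWorkflow(summed, unname(masks), tmplP, amask)
  expect_true(all(grepl("rigid", st2$audit)))
  expect_false(any(grepl("deformable", st2$audit)))
  kinds <- unlist(lapply(st2$chains, function(ch)
    vapply(ch@transforms, function(t) t@kind, character(1))))
  expect_true(all(kinds == "rigid"))
  expect_error(secondTemplateWorkflow(summed[1], masks[1], tmplP, amask),
               "too small")
})
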