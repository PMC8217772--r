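# Import, preprocessing and repeat-measurement detection.

test_that("NIfTI round trip preserves data, spacing and frame promotion", {
  f <- tempfile(fileext = ".nii.gz")
  vol <- VolumeImage(array(runif(4 * 4 * 6), c(4, 4, 6)),
                     c(2000, 2000, 2000))
  writeVolume(vol, f)
  img <- readVolume(f)
  expect_s4_class(img, "DynamicImage")
  expect_equal(nFrames(img), 1L)                   # 3-D promoted to 1 frame
  expect_equal(spacing(img), c(2000, 2000, 2000))
  expect_equal(voxels(img)[, , , 1], vol@voxels, tolerance = 1e-6)

  f4 <- tempfile(fileext = ".nii.gz")
  dyn <- smallDynamic(c(4, 4, 6), nframes = 6, spacing = c(2000, 2000, 2000))
  writeVolume(dyn, f4)
  img4 <- readVolume(f4)
  expect_equal(nFrames(img4), 6L)
  expect_equal(nrow(frameSchedule(img4)), 6L)

  bad <- tempfile(fileext = ".nii")
  writeLines("not a nifti", bad)
  expect_error(readVolume(bad), "unreadable")
})

test_that("peripheral slice exclusion trims both axial ends and composes", {
  img <- smallDynamic(c(6, 6, 159), nframes = 2)
  expect_equal(dim(excludePeripheralSlices(img, 5)@voxels)[3], 149L)
  img12 <- smallDynamic(c(6, 6, 12))
  expect_equal(dim(excludePeripheralSlices(img12, 5)@voxels)[3], 2L)
  expect_error(excludePeripheralSlices(smallDynamic(c(6, 6, 10)), 5),
               "axial extent")
  # composition: n then m equals n + m
  big <- smallDynamic(c(4, 4, 30))
  big@voxels[] <- seq_along(big@voxels)
  a <- excludePeripheralSlices(excludePeripheralSlices(big, 3), 4)
  b <- excludePeripheralSlices(big, 7)
  expect_identical(a@voxels, b@voxels)
})

test_that("speckle filter follows the 26-neighbour rule in a single pass", {
  # isolated voxel: removed; saturated 3x3x3 centre: retained
  a <- array(0, c(11, 11, 11))
  a[6, 6, 6] <- 1
  a[1:3, 1:3, 1:3] <- 1
  img <- DynamicImage(array(a, c(dim(a), 1)), c(1, 1, 1), frameTable(0, 1))
  res <- removeSpeckles(img)
  expect_equal(res$image@voxels[6, 6, 6, 1], 0)
  expect_equal(res$image@voxels[2, 2, 2, 1], 1)  # 26 neighbours
  # brute-force oracle: count foreground neighbours of each voxel and
  # compare with the kept/removed decision (threshold sweep)
  set.seed(42)
  b <- array(rbinom(7^3, 1, 0.35), c(7, 7, 7))
  imgb <- DynamicImage(array(b, c(dim(b), 1)) * 5, c(1, 1, 1),
                       frameTable(0, 1))
  for (minN in c(4L, 5L, 6L)) {
    out <- removeSpeckles(imgb, minNeighbors = minN)$image@voxels[, , , 1]
    for (v in which(b == 1)) {
      ix <- arrayInd(v, dim(b))
      cnt <- 0L
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        p <- ix + c(dx, dy, dz)
        if (any(p < 1) || any(p > 7)) next
        cnt <- cnt + b[p[1], p[2], p[3]]
      }
      expect_equal(out[ix[1], ix[2], ix[3]] > 0, cnt >= minN)
    }
  }
  # never removes a fully supported voxel, never increases values
  expect_true(all(res$image@voxels <= img@voxels))
})

test_that("frame summation matches a per-voxel loop and commutes with scaling", {
  set.seed(7)
  img <- smallDynamic(c(5, 5, 6), nframes = 3)
  img@voxels[] <- runif(length(img@voxels))
  s <- sumFrames(img)
  # loop oracle
  ref <- array(0, dim(img@voxels)[1:3])
  for (f in 1:3) ref <- ref + img@voxels[, , , f]
  expect_equal(s@voxels, ref)
  scaled <- img
  scaled@voxels <- scaled@voxels * 2.5
  expect_equal(sumFrames(scaled)@voxels, 2.5 * s@voxels)
})

test_that("group intensity factors equalise means onto the maximum", {
  mk <- function(m) VolumeImage(array(m, c(3, 3, 3)), c(1, 1, 1))
  fac <- groupIntensityFactors(list(mk(10), mk(20), mk(40)))
  expect_equal(fac, c(4, 2, 1))
  expect_equal(groupIntensityFactors(list(mk(3))), 1)
  expect_equal(groupIntensityFactors(list(mk(5), mk(5))), c(1, 1))
  expect_error(groupIntensityFactors(list(mk(0))), "degenerate")
  # applying factors equalises means (random images)
  set.seed(1)
  imgs <- lapply(1:4, function(i)
    VolumeImage(array(runif(27, 0, i), c(3, 3, 3)), c(1, 1, 1)))
  fac <- groupIntensityFactors(imgs)
  means <- mapply(function(im, f) mean(im@voxels * f), imgs, fac)
  expect_true(max(abs(means - max(sapply(imgs, function(i)
    mean(i@voxels))))) < 1e-9 * max(means))
})

test_that("repeat measurements group by name with control state first", {
  rec <- data.frame(name = c("Rat_No_1", "Rat_No_1", "Rat_No_2"),
                    group = "A", state = c("stroke", "healthy", "healthy"))
  series <- detectRepeatMeasurements(rec)
  expect_equal(series$Rat_No_1, c("healthy", "stroke"))
  expect_equal(series$Rat_No_2, "healthy")
  dup <- rbind(rec, rec[1, ])
  expect_error(detectRepeatMeasurements(dup), "duplicated")
})
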