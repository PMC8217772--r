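# The three semi-quantitative parameters and their invariants.

makeToyAtlas <- function() {
  # two regions of 100 full voxels each on a 10x10x4 grid, 1 mm iso voxels
  # (voxel volume 0.001 mL)
  f1 <- array(0, c(10, 10, 4)); f1[1:10, 1:10, 1] <- 1
  f2 <- array(0, c(10, 10, 4)); f2[1:10, 1:10, 2] <- 1
  mask <- (f1 + f2) > 0.5
  new("FractionalAtlas", fractions = list(`1` = f1, `2` = f2),
      brainMask = BinaryMask(mask, c(1000, 1000, 1000)),
      spacing = c(1000, 1000, 1000),
      labelTable = data.frame(id = 1:2, name = c("regionA", "cerebellum")))
}

test_that("region activity integrates fraction-weighted concentration", {
  fa <- makeToyAtlas()
  img <- VolumeImage(array(1000, c(10, 10, 4)), c(1000, 1000, 1000))
  ra <- regionActivity(img, fa, 1)
  expect_equal(ra$activity_Bq, 100 * 1000 * 0.001)   # 100 Bq
  expect_equal(ra$volume_mL, 0.1)
  expect_equal(ra$concentration_Bq_per_mL, 1000)
  # fractional voxel contributes proportionally
  fa2 <- fa
  fa2@fractions[["1"]][1, 1, 1] <- 0.5
  ra2 <- regionActivity(img, fa2, 1)
  expect_equal(ra2$activity_Bq, ra$activity_Bq - 0.5 * 1000 * 0.001)
  # partition of unity: region activities sum to the whole-VOI activity
  set.seed(3)
  img2 <- VolumeImage(array(runif(400, 0, 2000), c(10, 10, 4)),
                      c(1000, 1000, 1000))
  tot <- regionActivity(img2, fa, "whole_voi")$activity_Bq
  parts <- regionActivity(img2, fa, 1)$activity_Bq +
           regionActivity(img2, fa, 2)$activity_Bq
  expect_equal(parts, tot, tolerance = 1e-12)
  expect_error(regionActivity(img2, fa, 99), "not present")
})

test_that("A_N, SUV and UR reproduce the worked arithmetic", {
  expect_equal(normalizedActivity(1e6, 20e6), 0.05)
  expect_equal(normalizedActivity(0, 20e6), 0)
  expect_equal(normalizedActivity(20e6, 20e6), 1)
  expect_error(normalizedActivity(1, 0), "positive")
  # SUV worked example: 5 kBq/mL, 25 MBq, 250 g -> 0.05 g/mL
  expect_identical(suv(5000, 25e6, 250), 0.05)
  expect_equal(suv(25e6 / 250, 25e6, 250), 1)
  expect_equal(suv(5000, 25e6, 500), 2 * suv(5000, 25e6, 250))
  expect_equal(uptakeRatio(2000, 4000), 0.5)
  expect_equal(uptakeRatio(7, 7), 1)
  expect_error(uptakeRatio(1, 0), "positive")
})

test_that("cohort quantification tiles frames and respects invariants", {
  fa <- makeToyAtlas()
  fs <- frameTable(c(0, 600, 1200), c(600, 1200, 1800))
  set.seed(4)
  arr <- array(runif(400 * 3, 0, 2000), c(10, 10, 4, 3))
  img <- DynamicImage(arr, c(1000, 1000, 1000), fs)
  rec <- data.frame(animal_id = "a1", group = "g", state = "healthy",
                    injected_activity_Bq = 25e6, body_weight_g = 250)
  q <- quantifyCohort(list(a1 = list(healthy = img)), fa, rec,
                      list(c(0, 20), c(0, 30)))
  tab <- quantTable(q)
  expect_equal(nrow(tab), 2 * 2)   # 2 regions x 2 intervals
  # 0-20 min sums frames 1-2 only
  vol020 <- apply(arr[, , , 1:2], 1:3, sum)
  ra <- sum(vol020[, , 1]) * 0.001
  expect_equal(tab$A_N[tab$region == "1" & tab$interval == "0-20 min"],
               ra / 25e6)
  # whole-VOI UR: partition of unity means region URs sum to 1
  byIv <- split(tab, tab$interval)
  for (iv in byIv) expect_equal(sum(iv$UR), 1, tolerance = 1e-9)
  # interval not on frame boundaries errors and names the valid ones
  expect_error(quantifyCohort(list(a1 = list(healthy = img)), fa, rec,
                              list(c(0, 15))), "does not tile")
  # UR invariant under global rescaling; A_N and SUV scale linearly
  img2 <- img; img2@voxels <- img2@voxels * 3.7
  q2 <- quantifyCohort(list(a1 = list(healthy = img2)), fa, rec,
                       list(c(0, 20)))
  t1 <- quantTable(q)[quantTable(q)$interval == "0-20 min", ]
  t2 <- quantTable(q2)
  expect_equal(t2$UR, t1$UR, tolerance = 1e-12)
  expect_equal(t2$A_N, 3.7 * t1$A_N, tolerance = 1e-12)
  expect_equal(t2$SUV, 3.7 * t1$SUV, tolerance = 1e-12)
  # reference-region mode: UR of the reference against itself is 1
  qr <- quantifyCohort(list(a1 = list(healthy = img)), fa, rec,
                       list(c(0, 20)), referenceRegion = 2)
  tr <- quantTable(qr)
  expect_equal(tr$UR[tr$region == "2"], 1)
})

test_that("quantification CSV export is tidy and stable", {
  fa <- makeToyAtlas()
  img <- DynamicImage(array(1000, c(10, 10, 4, 1)), c(1000, 1000, 1000),
                      frameTable(0, 600))
  rec <- data.frame(animal_id = "a1", group = "g", state = "healthy",
                    injected_activity_Bq = 25e6, body_weight_g = 250)
  q <- quantifyCohort(list(a1 = list(healthy = img)), fa, rec,
                      list(c(0, 10)))
  f <- tempfile(fileext = ".csv")
  writeQuantCsv(q, f)
  tab <- read.csv(f)
  expect_equal(names(tab), c("animal_id", "group", "state", "region",
                             "interval", "parameter", "value"))
  expect_equal(nrow(tab), 2 * 3)
})
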