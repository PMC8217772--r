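# Reference selection, centring, template averaging, inverted-VOI
# segmentation.

test_that("VOI orientation recovers principal-axis angles", {
  m <- ellipsoidMask(64, c(10, 6, 15))  # long axis along z, middle x
  o <- voiOrientation(m)
  expect_lt(o$theta_z, 1); expect_lt(o$theta_x, 1); expect_lt(o$theta_y, 1)
  expect_true(all(diff(o$axis_lengths) < 0))
  # rotated about y by 10 degrees: theta_z about 10
  mr <- moveArray(m, c(0, 10, 0), linear = FALSE) > 0.5
  dim(mr) <- dim(m)
  or <- voiOrientation(mr)
  expect_lt(abs(or$theta_z - 10), 1)
  # sphere is degenerate
  expect_error(voiOrientation(ellipsoidMask(32, c(9, 9, 9))), "isotropic")
  expect_error(voiOrientation(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("reference selection picks the best-aligned VOI", {
  sp <- c(1, 1, 1)
  m0 <- ellipsoidMask(48, c(10, 6, 15))
  mk <- function(ang) {
    r <- moveArray(m0, ang, linear = FALSE) > 0.5
    dim(r) <- dim(m0)
    BinaryMask(r, sp)
  }
  masks <- list(mk(c(8, 6, 0)), mk(c(0, 0, 0)), mk(c(12, 0, 4)))
  expect_equal(selectReference(masks), 2L)
  expect_equal(selectReference(masks[1]), 1L)
  # permutation equivariance
  perm <- c(2, 3, 1)
  expect_equal(perm[selectReference(masks[perm])], 2L)
})

test_that("VOI centring shifts the centroid to the grid centre", {
  m <- ellipsoidMask(40, c(8, 6, 9), center = c(14, 25, 18))
  v <- array(0, c(40, 40, 40)); v[m] <- 2
  res <- centerVoi(VolumeImage(v, c(1, 1, 1)), BinaryMask(m, c(1, 1, 1)))
  cen <- petquant:::maskCentroid(res$mask@voxels)
  expect_true(all(abs(cen - 20.5) <= 0.75))
  # already centred: identity
  mc <- ellipsoidMask(40, c(8, 6, 9))
  res2 <- centerVoi(VolumeImage(array(as.double(mc), dim(mc)), c(1, 1, 1)),
                    BinaryMask(mc, c(1, 1, 1)))
  expect_equal(res2$shift, c(0L, 0L, 0L))
  # shift pushing other image content out of bounds crops with a warning
  voiM <- ellipsoidMask(30, c(6, 6, 6), center = c(9, 15, 15))
  vimg <- array(as.double(voiM), dim(voiM))
  vimg[28:30, 14:16, 14:16] <- 3  # content at the far edge
  expect_warning(centerVoi(VolumeImage(vimg, c(1, 1, 1)),
                           BinaryMask(voiM, c(1, 1, 1))),
                 "cropped")
})

test_that("template building averages aligned members around the reference", {
  img <- blobImage(32)
  m <- BinaryMask(img@voxels > 0.3, img@spacing)
  # single control: template is the centred control
  t1 <- buildTemplate(list(img), list(m), 1L)
  cen <- centerVoi(img, m)
  expect_equal(t1@image@voxels, cen$image@voxels)
  expect_equal(t1@referenceId, "control_1")
  # N copies of one image: template equals that image
  t3 <- buildTemplate(list(img, img, img), list(m, m, m), 1L,
                      iterations = 30L)
  expect_lt(max(abs(t3@image@voxels - cen$image@voxels)),
            0.02 * max(img@voxels))
  # translated copy: mean stays close to the reference
  mv <- VolumeImage(moveArray(img@voxels, trans = c(2, -1, 1)), img@spacing)
  mm <- BinaryMask(mv@voxels > 0.3, img@spacing)
  t2 <- buildTemplate(list(img, mv), list(m, mm), 1L, iterations = 80L)
  expect_lt(max(abs(t2@image@voxels - cen$image@voxels)),
            0.05 * max(img@voxels))
  # mean bounded by per-voxel member min/max holds trivially for identical
  # members; centroid within a voxel of the reference VOI centroid
  tcen <- petquant:::maskCentroid(t2@image@voxels > 0.3)
  rcen <- petquant:::maskCentroid(cen$image@voxels > 0.3)
  expect_lt(max(abs(tcen - rcen)), 1)
})

test_that("inverted-intensity template VOI isolates the dim brain tissue", {
  spec <- phantomSpec(tracerMode = "target_selective", seed = 30)
  tp <- petquant:::tracerPattern(spec)$pattern
  voi <- segmentTemplateVoiInverted(VolumeImage(tp, spec$petSpacing))
  truth <- petquant:::petGridLabels(spec) > 0
  expect_gte(diceCoef(voi@voxels, truth), 0.8)
  # single connected component
  expect_equal(max(petquant:::cpp_cc_label(voi@voxels, 26L)), 1L)
  # uniform nonzero image: degenerate, nothing survives the exclusion
  expect_error(segmentTemplateVoiInverted(
    VolumeImage(array(4, c(10, 10, 10)), c(1, 1, 1))), "variation|empty")
  # lesion at the grid centre: seed relocates, mask still one component
  spec2 <- phantomSpec(tracerMode = "target_selective", seed = 31,
                       lesion = list(center_offset_vox = c(0, 0, 0),
                                     radius_vox = 3.5, contrast = 10))
  tp2 <- petquant:::tracerPattern(spec2)$pattern
  voi2 <- segmentTemplateVoiInverted(VolumeImage(tp2, spec2$petSpacing))
  expect_equal(max(petquant:::cpp_cc_label(voi2@voxels, 26L)), 1L)
  expect_gt(sum(voi2@voxels), 0)
})
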