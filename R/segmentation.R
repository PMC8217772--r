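# Brain-VOI segmentation in summed PET images by rotational contour
# matching against the resized atlas mask (module: voi_segmentation).
# Distinct procedures for metabolic (broad, symmetric uptake) and
# target-selective (focal uptake, low background) radiotracers.

#' SegmentationResult: outcome of a VOI segmentation
#'
#' @slot voiMask \code{BinaryMask} of the segmented VOI.
#' @slot bestRotation numeric(3) per-axis angles in degrees (x, y, z), each
#'   in [-20, 20].
#' @slot matchScore boundary-F1 contour match score in [0, 1].
#' @slot thresholdUsed the adaptive intensity threshold that produced the
#'   candidate object.
#' @export
setClass("SegmentationResult",
  representation(voiMask = "BinaryMask", bestRotation = "numeric",
                 matchScore = "numeric", thresholdUsed = "numeric"))

setValidity("SegmentationResult", function(object) {
  msgs <- character()
  if (object@matchScore < 0 || object@matchScore > 1)
    msgs <- c(msgs, "matchScore must lie in [0, 1]")
  if (any(abs(object@bestRotation) > 20 + 1e-9))
    msgs <- c(msgs, "rotation components must lie in [-20, 20] degrees")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d VOI voxels, score %.3f, rotation (%g, %g, %g) deg, threshold %.4g\n",
              sum(object@voiMask@voxels), object@matchScore,
              object@bestRotation[1], object@bestRotation[2],
              object@bestRotation[3], object@thresholdUsed))
})

#' Zero the caudal third of a volume
#'
#' The animal is centred manually in the scanner, so the caudal last third
#' of the axial extent holds no brain; those slices are zeroed before
#' thresholding.
#'
#' @param img a \code{VolumeImage}.
#' @return The \code{VolumeImage} with the last \code{floor(nz/3)} axial
#'   slices zeroed.
#' @export
dropCaudalThird <- function(img) {
  assertVolume(img)
  nz <- dim(img@voxels)[3L]
  if (nz < 3L) stop("axial extent must be at least 3")
  nDrop <- nz %/% 3L
  v <- img@voxels
  v[, , (nz - nDrop + 1L):nz] <- 0
  VolumeImage(v, img@spacing)
}

#' Multilevel Otsu thresholds
#'
#' Thresholds maximising the between-class variance of a 256-bin histogram
#' of the sample (equivalently minimising total within-class weighted
#' variance, solved exactly by dynamic programming over bin cut points).
#'
#' @param values numeric sample (e.g. the nonzero voxels of a volume).
#' @param nThresholds number of thresholds (default 1).
#' @param nBins histogram bins (default 256).
#' @return numeric vector of \code{nThresholds} thresholds, increasing.
#' @export
otsuThresholds <- function(values, nThresholds = 1L, nBins = 256L) {
  values <- values[is.finite(values)]
  r <- range(values)
  if (length(unique(values)) < 2L || r[2] <= r[1])
    stop("need at least 2 distinct values for Otsu thresholding")
  k <- as.integer(nThresholds)
  br <- seq(r[1], r[2], length.out = nBins + 1L)
  h <- tabulate(pmin(findInterval(values, br, rightmost.closed = TRUE), nBins),
                nbins = nBins)
  mid <- (br[-1] + br[-length(br)]) / 2
  W <- cumsum(h); M <- cumsum(h * mid); S <- cumsum(h * mid^2)
  segCost <- function(i, j) { # within-class weighted SS for bins i..j
    w <- W[j] - if (i > 1) W[i - 1] else 0
    if (w <= 0) return(0)
    m <- M[j] - if (i > 1) M[i - 1] else 0
    s <- S[j] - if (i > 1) S[i - 1] else 0
    s - m * m / w
  }
  if (k == 1L) {
    # single threshold: evaluate every cut; empty-gap cuts tie, take the
    # middle of the optimal plateau
    costs <- vapply(seq_len(nBins - 1L),
                    function(j) segCost(1L, j) + segCost(j + 1L, nBins),
                    numeric(1))
    opt <- which(costs <= min(costs) + 1e-12)
    cut <- opt[ceiling(length(opt) / 2)]
    return(br[cut + 1L])
  }
  nc <- k + 1L
  INF <- Inf
  cost <- matrix(INF, nc, nBins)
  back <- matrix(0L, nc, nBins)
  for (j in seq_len(nBins)) cost[1L, j] <- segCost(1L, j)
  if (nc > 1L) for (c in 2:nc) for (j in c:nBins) {
    best <- INF; bi <- 0L
    for (i in c:j) {
      v <- cost[c - 1L, i - 1L] + segCost(i, j)
      if (v < best) { best <- v; bi <- i }
    }
    cost[c, j] <- best; back[c, j] <- bi
  }
  cuts <- integer(k)
  j <- nBins
  if (k > 0) for (c in nc:2) {
    i <- back[c, j]
    cuts[c - 1L] <- i - 1L
    j <- i - 1L
  }
  br[cuts + 1L]
}

#' Adaptive volume threshold matching a target object size
#'
#' Starting from the Otsu threshold, the threshold is adjusted by bisection
#' on the intensity range until the largest connected foreground component
#' is within 20\% of \code{targetVoxelCount} (or 50 iterations elapse); the
#' largest component is returned as the candidate object.
#'
#' @param img a \code{VolumeImage}.
#' @param targetVoxelCount desired object size, e.g. the resized atlas mask
#'   voxel count.
#' @param tolFrac acceptance band around the target (default 0.2).
#' @param maxIter bisection cap (default 50).
#' @return \code{list(mask = BinaryMask, threshold = numeric)}.
#' @export
adaptiveVolumeThreshold <- function(img, targetVoxelCount, tolFrac = 0.2,
                                    maxIter = 50L) {
  assertVolume(img)
  stopifnot(targetVoxelCount > 0)
  v <- img@voxels
  nz <- v[v != 0]
  if (length(nz) == 0L) stop("segmentation failure: image has no structure")
  # binary-valued images have no Otsu level; start halfway to the value
  thr <- if (length(unique(nz)) < 2L) min(nz) / 2 else otsuThresholds(nz, 1L)
  lo <- min(v); hi <- max(v) # full intensity range: piecewise-constant
                             # images need thresholds below the lowest
                             # nonzero level to capture it
  best <- NULL; bestErr <- Inf
  countAt <- function(t) {
    m <- v > t
    dim(m) <- dim(v)
    cc <- largestComponent(m)
    list(mask = cc, n = sum(cc))
  }
  for (i in seq_len(maxIter)) {
    res <- countAt(thr)
    err <- abs(res$n - targetVoxelCount) / targetVoxelCount
    if (err < bestErr) { bestErr <- err; best <- list(mask = res$mask, thr = thr) }
    if (err <= tolFrac) break
    if (res$n > targetVoxelCount) lo <- thr else hi <- thr
    newThr <- (lo + hi) / 2
    if (abs(newThr - thr) < 1e-12 * max(1, abs(hi))) break
    thr <- newThr
  }
  if (bestErr > 0.5)
    stop("segmentation failure: no threshold yields an object within 50% of ",
         targetVoxelCount, " voxels (best off by ",
         round(100 * bestErr), "%)")
  list(mask = BinaryMask(best$mask, img@spacing), threshold = best$thr)
}

#' Boundary-F1 contour match score
#'
#' Precision is the fraction of mask A's boundary voxels lying within
#' \code{tolVoxels} (Euclidean) of mask B's boundary, recall the symmetric
#' quantity; the score is their harmonic mean. Returns 1 when both
#' boundaries are empty and 0 when exactly one is.
#'
#' @param maskA,maskB logical arrays or \code{BinaryMask} objects of the
#'   same shape.
#' @param tolVoxels distance tolerance in voxels (default 1).
#' @return score in [0, 1].
#' @export
bfScore <- function(maskA, maskB, tolVoxels = 1.0) {
  a <- if (is(maskA, "BinaryMask")) maskA@voxels else maskA
  b <- if (is(maskB, "BinaryMask")) maskB@voxels else maskB
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  storage.mode(a) <- "logical"; storage.mode(b) <- "logical"
  ba <- which(cpp_boundary(a), arr.ind = TRUE) - 1
  bb <- which(cpp_boundary(b), arr.ind = TRUE) - 1
  bfScoreCoords(ba, bb, tolVoxels)
}

bfScoreCoords <- function(coordsA, coordsB, tolVoxels = 1.0) {
  nA <- nrow(coordsA); nB <- nrow(coordsB)
  if (nA == 0 && nB == 0) return(1)
  if (nA == 0 || nB == 0) return(0)
  precision <- cpp_match_fraction(coordsA, coordsB, tolVoxels)
  recall <- cpp_match_fraction(coordsB, coordsA, tolVoxels)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Rotation search for contour matching
#'
#' The atlas mask is rotated through a per-axis angle grid (default -20 to
#' 20 degrees in 2-degree steps, nearest-neighbour resampling about the
#' volume centre), centroid-aligned to the candidate object (or anchored at
#' \code{anchor}) and scored with \code{\link{bfScore}}; the maximising
#' placement is returned. Ties are broken by smallest total absolute angle,
#' then by lexicographic (x, y, z) angle order.
#'
#' @param candidate \code{BinaryMask} (or logical array): the thresholded
#'   PET object.
#' @param atlasMask \code{BinaryMask} (or logical array): the resized atlas
#'   support.
#' @param stepDeg grid step in degrees (default 2).
#' @param rangeDeg symmetric angle range (default 20).
#' @param mode \code{"sequential"} (coordinate descent over axes z, x, y;
#'   63 evaluations; the default) or \code{"exhaustive"} (full 21^3 grid).
#' @param anchor optional numeric(3): 1-based voxel position at which the
#'   rotated atlas centroid is anchored; default is the candidate centroid.
#' @param tolVoxels boundary-F1 tolerance.
#' @return \code{list(bestRotation, bestOffset, bestScore)} where
#'   \code{bestOffset} is the voxel translation applied to the rotated
#'   atlas mask.
#' @export
rotationSearch <- function(candidate, atlasMask, stepDeg = 2, rangeDeg = 20,
                           mode = c("sequential", "exhaustive"),
                           anchor = NULL, tolVoxels = 1.0) {
  mode <- match.arg(mode)
  cand <- if (is(candidate, "BinaryMask")) candidate@voxels else candidate
  atl <- if (is(atlasMask, "BinaryMask")) atlasMask@voxels else atlasMask
  storage.mode(cand) <- "logical"; storage.mode(atl) <- "logical"
  if (!any(atl)) stop("atlas mask is empty")
  if (!any(cand)) stop("candidate mask is empty")
  if (is.null(anchor)) anchor <- maskCentroid(cand)
  candBnd <- which(cpp_boundary(cand), arr.ind = TRUE) - 1
  angles <- seq(-rangeDeg, rangeDeg, by = stepDeg)
  evalRot <- function(rot) { # rot = c(x, y, z) degrees
    ra <- rotateTranslateArray(array(as.double(atl), dim(atl)), rot,
                               linear = FALSE) > 0.5
    dim(ra) <- dim(atl)
    if (!any(ra)) return(list(score = -1, offset = c(0, 0, 0)))
    off <- anchor - maskCentroid(ra)
    bnd <- which(cpp_boundary(ra), arr.ind = TRUE) - 1
    bnd <- sweep(bnd, 2, off, `+`)
    list(score = bfScoreCoords(candBnd, bnd, tolVoxels), offset = off)
  }
  better <- function(cur, new, rotCur, rotNew) {
    if (new$score > cur$score + 1e-12) return(TRUE)
    if (new$score < cur$score - 1e-12) return(FALSE)
    sN <- sum(abs(rotNew)); sC <- sum(abs(rotCur))
    if (sN < sC - 1e-12) return(TRUE)
    if (sN > sC + 1e-12) return(FALSE)
    # lexicographic on (x, y, z)
    for (i in 1:3) {
      if (rotNew[i] < rotCur[i] - 1e-12) return(TRUE)
      if (rotNew[i] > rotCur[i] + 1e-12) return(FALSE)
    }
    FALSE
  }
  bestRot <- c(0, 0, 0)
  bestRes <- evalRot(bestRot)
  if (mode == "exhaustive") {
    for (az in angles) for (ax in angles) for (ay in angles) {
      rot <- c(ax, ay, az)
      if (all(rot == 0)) next
      res <- evalRot(rot)
      if (better(bestRes, res, bestRot, rot)) { bestRes <- res; bestRot <- rot }
    }
  } else {
    for (axis in c(3L, 1L, 2L)) { # z, then x, then y
      for (a in angles) {
        rot <- bestRot; rot[axis] <- a
        if (all(rot == bestRot)) next
        res <- evalRot(rot)
        if (better(bestRes, res, bestRot, rot)) { bestRes <- res; bestRot <- rot }
      }
    }
  }
  list(bestRotation = bestRot, bestOffset = bestRes$offset,
       bestScore = max(bestRes$score, 0))
}

# place the atlas mask under a rotation-search result: rotate (NN) and shift
# by the rounded offset
placeAtlasMask <- function(atl, rot, offset) {
  ra <- rotateTranslateArray(array(as.double(atl), dim(atl)), rot,
                             translation = offset, linear = FALSE) > 0.5
  dim(ra) <- dim(atl)
  ra
}

#' Segment the brain VOI for a metabolic radiotracer
#'
#' Pipeline: caudal-third removal, adaptive volume threshold targeting the
#' atlas mask size, rotation search for the best contour match, and VOI
#' extraction as the candidate voxels under the best-placed atlas mask
#' (dilated by one voxel).
#'
#' @param img summed, preprocessed \code{VolumeImage}.
#' @param atlasMask \code{BinaryMask}: resized atlas support on the PET grid
#'   (same shape as \code{img}).
#' @param searchMode passed to \code{\link{rotationSearch}}.
#' @return A \code{\linkS4class{SegmentationResult}}.
#' @export
segmentVoiMetabolic <- function(img, atlasMask, searchMode = "sequential") {
  assertVolume(img)
  atl <- if (is(atlasMask, "BinaryMask")) atlasMask@voxels else atlasMask
  storage.mode(atl) <- "logical"
  red <- dropCaudalThird(img)
  thr <- adaptiveVolumeThreshold(red, sum(atl))
  cand <- thr$mask@voxels
  rs <- rotationSearch(cand, atl, mode = searchMode)
  placed <- placeAtlasMask(atl, rs$bestRotation, rs$bestOffset)
  voi <- cand & morph3(placed, "dilate")
  voi <- largestComponent(voi)
  new("SegmentationResult",
      voiMask = BinaryMask(voi, img@spacing),
      bestRotation = rs$bestRotation, matchScore = rs$bestScore,
      thresholdUsed = thr$threshold)
}

# Morphological reduction of the thresholded head object for the
# target-selective procedure: fill cavities, open with a 3x3x3 element,
# split touching components by marker growing, keep components overlapping
# the central axial band.
morphologicalReduction <- function(candMask) {
  m <- cpp_fill_holes(candMask)
  er <- morph3(m, "erode")
  if (!any(er)) er <- m
  markers <- cpp_cc_label(er, 26L)
  split <- cpp_grow_markers(m, markers)
  nz <- dim(m)[3L]
  zs <- which(apply(m, 3, any))
  if (length(zs) == 0) return(m)
  zmid <- range(zs)
  band <- seq(floor(zmid[1] + diff(zmid) / 3), ceiling(zmid[2] - diff(zmid) / 3))
  band <- band[band >= 1 & band <= nz]
  keepIds <- unique(as.integer(split[, , band]))
  keepIds <- keepIds[keepIds > 0]
  if (length(keepIds) == 0) keepIds <- unique(as.integer(split[split > 0]))
  out <- array(split %in% keepIds & m, dim(m))
  out
}

#' Segment the brain VOI for a target-selective radiotracer
#'
#' Handles low, focal tracer uptake in the VOI: after caudal-third removal
#' and adaptive thresholding, the bright head object is reduced
#' morphologically (cavity fill, opening, marker-based split of touching
#' components, central-band selection); interior voxels of the reduced
#' object seed the rotational contour match, anchoring the atlas mask at
#' each seed; the best (seed, rotation) pair defines the VOI as in the
#' metabolic case.
#'
#' @inheritParams segmentVoiMetabolic
#' @return A \code{\linkS4class{SegmentationResult}}.
#' @export
segmentVoiTargetSelective <- function(img, atlasMask,
                                      searchMode = "sequential") {
  assertVolume(img)
  atl <- if (is(atlasMask, "BinaryMask")) atlasMask@voxels else atlasMask
  storage.mode(atl) <- "logical"
  if (all(img@voxels == 0)) stop("segmentation failure: empty image")
  red <- dropCaudalThird(img)
  thr <- adaptiveVolumeThreshold(red, sum(atl), tolFrac = 0.35)
  reduced <- morphologicalReduction(thr$mask@voxels)
  interior <- morph3(reduced, "erode")
  if (!any(interior)) interior <- reduced
  if (!any(interior)) stop("segmentation failure: no seed points found")
  # one seed per interior component (its centroid), the distinct candidate
  # anchor positions of the reduced object
  lab <- cpp_cc_label(interior, 26L)
  seeds <- lapply(seq_len(max(lab)), function(id) {
    m <- lab == id; dim(m) <- dim(lab); maskCentroid(m)
  })
  best <- NULL
  for (s in seeds) {
    rs <- rotationSearch(reduced, atl, mode = searchMode, anchor = s)
    if (is.null(best) || rs$bestScore > best$bestScore) best <- rs
  }
  placed <- placeAtlasMask(atl, best$bestRotation, best$bestOffset)
  voi <- reduced & morph3(placed, "dilate")
  voi <- largestComponent(voi)
  new("SegmentationResult",
      voiMask = BinaryMask(voi, img@spacing),
      bestRotation = best$bestRotation, matchScore = best$bestScore,
      thresholdUsed = thr$threshold)
}
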