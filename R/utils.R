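# Internal constructors and small numeric helpers shared across modules.

#' Construct a DynamicImage
#'
#' @param voxels 3-D or 4-D numeric array; 3-D input becomes one frame.
#' @param spacing numeric(3), micrometres.
#' @param frameSchedule data.frame (start_s, end_s), one row per frame.
#' @param meta free-form provenance list.
#' @return A \code{\linkS4class{DynamicImage}}.
#' @export
DynamicImage <- function(voxels, spacing, frameSchedule, meta = list()) {
  if (length(dim(voxels)) == 3L)
    dim(voxels) <- c(dim(voxels), 1L)
  new("DynamicImage", voxels = voxels, spacing = as.numeric(spacing),
      frameSchedule = frameSchedule, meta = meta)
}

#' Construct a VolumeImage
#' @param voxels 3-D numeric array.
#' @param spacing numeric(3), micrometres.
#' @return A \code{\linkS4class{VolumeImage}}.
#' @export
VolumeImage <- function(voxels, spacing) {
  new("VolumeImage", voxels = voxels, spacing = as.numeric(spacing))
}

#' Construct a BinaryMask
#' @param voxels 3-D logical (or coercible) array.
#' @param spacing numeric(3), micrometres.
#' @return A \code{\linkS4class{BinaryMask}}.
#' @export
BinaryMask <- function(voxels, spacing) {
  storage.mode(voxels) <- "logical"
  new("BinaryMask", voxels = voxels, spacing = as.numeric(spacing))
}

#' Construct a LabelAtlas
#' @param labels 3-D integer array (0 = background).
#' @param spacing numeric(3), micrometres.
#' @param labelTable data.frame (id, name).
#' @return A \code{\linkS4class{LabelAtlas}}.
#' @export
LabelAtlas <- function(labels, spacing, labelTable) {
  storage.mode(labels) <- "integer"
  new("LabelAtlas", labels = labels, spacing = as.numeric(spacing),
      labelTable = labelTable)
}

#' Frame schedule helper
#' @param start_s,end_s numeric vectors of frame interval bounds (seconds).
#' @return data.frame (start_s, end_s).
#' @export
frameTable <- function(start_s, end_s) {
  data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s))
}

# min-max normalisation to [0, 1]; constant volumes map to 0
normalize01 <- function(v) {
  r <- range(v)
  if (r[2] <= r[1]) return(array(0, dim(v)))
  (v - r[1]) / (r[2] - r[1])
}

#' Dice coefficient of two masks
#' @param a,b logical arrays (or \code{BinaryMask} voxels) of equal shape.
#' @return Dice overlap in [0, 1].
#' @export
diceCoef <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# centroid of a logical array, 1-based voxel coordinates
maskCentroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no centroid")
  colMeans(idx)
}

# 0-based rotation matrix about the grid centre for per-axis angles (degrees),
# applied z then x then y (order fixed; small angles commute to within the
# search grid resolution)
rotationMatrix3 <- function(angles_deg) {
  a <- angles_deg * pi / 180
  Rx <- matrix(c(1, 0, 0,
                 0, cos(a[1]), -sin(a[1]),
                 0, sin(a[1]), cos(a[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(a[2]), 0, sin(a[2]),
                 0, 1, 0,
                 -sin(a[2]), 0, cos(a[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(a[3]), -sin(a[3]), 0,
                 sin(a[3]), cos(a[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  Ry %*% Rx %*% Rz
}

# Resample a 3-D array under a rotation about its centre plus translation
# (voxel units). `angles_deg` rotate the content; the resampling map is the
# inverse rotation. translation shifts content by +t.
rotateTranslateArray <- function(vol, angles_deg, translation = c(0, 0, 0),
                                 linear = TRUE) {
  d <- dim(vol)
  ctr <- (d - 1) / 2
  R <- rotationMatrix3(angles_deg)
  A <- solve(R)
  # out(p) = vol(Ainv (p - t - ctr) + ctr)
  b <- as.numeric(ctr - A %*% (ctr + translation))
  storage.mode(vol) <- "double"
  cpp_resample_affine(vol, as.integer(d), A, b, linear)
}

assertVolume <- function(x, what = "img") {
  if (!is(x, "VolumeImage")) stop(what, " must be a VolumeImage")
  invisible(x)
}

morph3 <- function(mask, op = c("dilate", "erode"), connectivity = 26L) {
  op <- match.arg(op)
  storage.mode(mask) <- "logical"
  cpp_morph(mask, op == "dilate", as.integer(connectivity))
}

largestComponent <- function(mask, connectivity = 26L) {
  storage.mode(mask) <- "logical"
  lab <- cpp_cc_label(mask, as.integer(connectivity))
  if (max(lab) == 0L) return(mask & FALSE)
  tab <- tabulate(lab[lab > 0L])
  keep <- which.max(tab)
  out <- lab == keep
  dim(out) <- dim(mask)
  out
}
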