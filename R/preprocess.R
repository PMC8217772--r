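# Preprocessing applied before any alignment (module: image_io_preprocess):
# peripheral slice exclusion, speckle removal on the 26-neighbourhood,
# frame summation, within-group intensity factors, repeat-measurement
# detection.

#' Exclude peripheral axial slices
#'
#' Removes the first and last \code{n} slices along the axial (z) axis from
#' every frame, improving signal-to-noise at the axial field-of-view edges.
#'
#' @param img a \code{\linkS4class{DynamicImage}}.
#' @param n number of slices to drop at each axial end (default 5).
#' @return The trimmed \code{DynamicImage}.
#' @export
excludePeripheralSlices <- function(img, n = 5L) {
  n <- as.integer(n)
  nz <- dim(img@voxels)[3L]
  if (nz <= 2L * n)
    stop("axial extent (", nz, ") must exceed 2 * n = ", 2L * n)
  keep <- (n + 1L):(nz - n)
  DynamicImage(img@voxels[, , keep, , drop = FALSE], img@spacing,
               img@frameSchedule, img@meta)
}

#' Remove speckle voxels by 26-neighbourhood support
#'
#' A binary foreground mask is formed from the nonzero voxels of the
#' frame-summed image; any foreground voxel with fewer than
#' \code{minNeighbors} foreground voxels among its 26 neighbours is zeroed
#' in all frames. A single pass: neighbour counts are evaluated on the
#' original mask, not iteratively.
#'
#' @param img a \code{\linkS4class{DynamicImage}}.
#' @param minNeighbors minimum foreground 26-neighbours to retain a voxel
#'   (default 5).
#' @return \code{list(image = DynamicImage, report = list)} where the report
#'   holds \code{n_speckle_voxels_removed}.
#' @export
removeSpeckles <- function(img, minNeighbors = 5L) {
  summed <- apply(img@voxels, 1:3, sum)
  mask <- summed != 0
  dim(mask) <- dim(summed)
  cnt <- cpp_neighbor_count26(mask)
  drop <- mask & (cnt < as.integer(minNeighbors))
  vox <- img@voxels
  if (any(drop)) {
    for (f in seq_len(dim(vox)[4L])) {
      fr <- vox[, , , f]
      fr[drop] <- 0
      vox[, , , f] <- fr
    }
  }
  list(image = DynamicImage(vox, img@spacing, img@frameSchedule, img@meta),
       report = list(n_speckle_voxels_removed = sum(drop)))
}

#' Sum all time frames of a dynamic image
#'
#' The frame-summed image maximises counts for alignment; it is used only
#' for alignment, never for quantification.
#'
#' @param img a \code{\linkS4class{DynamicImage}}.
#' @return A \code{\linkS4class{VolumeImage}}.
#' @export
sumFrames <- function(img) {
  s <- apply(img@voxels, 1:3, sum)
  VolumeImage(s, img@spacing)
}

#' Within-group intensity multiplication factors
#'
#' For summed image i with mean intensity m_i, the factor is
#' \code{max_j(m_j) / m_i}, computed within one experimental group; the image
#' with the highest mean gets factor 1 and applying the factors equalises
#' all group means. Compensates variation in applied radioactivity; the
#' factors affect alignment only, never quantification.
#'
#' @param summedImages list of \code{VolumeImage} belonging to one group.
#' @param meanOver \code{"all_voxels"} (default) or \code{"nonzero_only"}.
#' @return numeric vector of positive factors, one per image.
#' @export
groupIntensityFactors <- function(summedImages,
                                  meanOver = c("all_voxels", "nonzero_only")) {
  meanOver <- match.arg(meanOver)
  if (length(summedImages) < 1L) stop("need at least one image")
  m <- vapply(summedImages, function(im) {
    v <- im@voxels
    if (meanOver == "nonzero_only") v <- v[v != 0]
    if (length(v) == 0) 0 else mean(v)
  }, numeric(1))
  if (any(m <= 0)) stop("degenerate input: an image has mean intensity <= 0")
  max(m) / m
}

#' Detect repeat measurements of the same animal
#'
#' Records sharing a name form a longitudinal series, ordered with the
#' control state first (then input order).
#'
#' @param records data.frame with columns \code{name}, \code{group},
#'   \code{state}.
#' @param controlState the state treated as control (default
#'   \code{"healthy"}); matched case-insensitively, and \code{"control"} or
#'   \code{"sham"} are also recognised.
#' @return named list mapping each name to its ordered character vector of
#'   states.
#' @export
detectRepeatMeasurements <- function(records, controlState = "healthy") {
  stopifnot(all(c("name", "state") %in% names(records)))
  if (any(!nzchar(records$name))) stop("names must be non-empty")
  key <- paste(records$name, records$state, sep = "\r")
  if (anyDuplicated(key))
    stop("ambiguous input: duplicated (name, state) pair: ",
         records$name[duplicated(key)][1])
  ctl <- tolower(c(controlState, "control", "sham", "healthy"))
  out <- lapply(split(records$state, records$name), function(states) {
    isCtl <- tolower(states) %in% ctl
    c(states[isCtl], states[!isCtl])
  })
  out[unique(records$name)]
}

#' Full preprocessing of one dynamic image
#'
#' Convenience wrapper: peripheral slice exclusion followed by speckle
#' removal; returns the image together with a preprocessing report.
#'
#' @param img a \code{\linkS4class{DynamicImage}}.
#' @param nSlices slices excluded at each axial end.
#' @param minNeighbors speckle-filter neighbour threshold.
#' @return \code{list(image, report)}; the report holds
#'   \code{n_slices_removed}, \code{n_speckle_voxels_removed} and a
#'   placeholder \code{multiplication_factor = 1} (filled in per group by
#'   \code{\link{groupIntensityFactors}}).
#' @export
preprocessImage <- function(img, nSlices = 5L, minNeighbors = 5L) {
  trimmed <- excludePeripheralSlices(img, nSlices)
  sp <- removeSpeckles(trimmed, minNeighbors)
  list(image = sp$image,
       report = list(n_slices_removed = 2L * as.integer(nSlices),
                     n_speckle_voxels_removed =
                       sp$report$n_speckle_voxels_removed,
                     multiplication_factor = 1))
}
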