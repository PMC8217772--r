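# Resizing the high-resolution MRI/atlas to the PET grid with per-voxel
# fractional region membership (module: atlas_resampling).

#' Atlas-to-PET scale factor
#'
#' The single isotropic resize factor \code{1 / round(pet / mri)} derived
#' from the PET in-plane resolution and the MRI resolution, e.g. 776 um PET
#' with 39 um MRI gives 1/20 and with 25 um MRI gives 1/31.
#'
#' @param petInplaneResUm PET in-plane voxel size, micrometres.
#' @param mriResUm MRI voxel size, micrometres.
#' @return list with \code{scale_factor} (the rational 1/k), \code{denominator}
#'   (k) and \code{method = "linear"}.
#' @examples
#' computeScaleFactor(776, 39)$denominator  # 20
#' @export
computeScaleFactor <- function(petInplaneResUm, mriResUm) {
  if (petInplaneResUm <= 0 || mriResUm <= 0)
    stop("resolutions must be positive")
  ratio <- petInplaneResUm / mriResUm
  if (ratio < 1)
    stop("unsupported input: MRI resolution coarser than PET (ratio ",
         signif(ratio, 4), " < 1)")
  k <- round(ratio)
  list(scale_factor = 1 / k, denominator = as.integer(k), method = "linear")
}

# sample coordinates (0-based, input grid) of an output grid resized by
# `factor`: output voxel centre i maps to (i + 0.5)/factor - 0.5, the
# standard align-centres convention for resizing
resizeCoords <- function(nIn, factor) {
  nOut <- max(1L, as.integer(floor(nIn * factor)))
  list(n = nOut, at = (seq_len(nOut) - 0.5) / factor - 0.5)
}

#' Resize a volume by a scale factor with trilinear interpolation
#'
#' Downsamples on every axis by \code{spec$scale_factor}; output spacing is
#' input spacing divided by the factor.
#'
#' @param vol a \code{VolumeImage} (label atlases are resized per region via
#'   \code{\link{resizeSubregions}}).
#' @param spec result of \code{\link{computeScaleFactor}} (or a list with a
#'   \code{scale_factor} in (0, 1]).
#' @return The resized \code{VolumeImage}.
#' @export
resizeVolume <- function(vol, spec) {
  assertVolume(vol, "vol")
  f <- spec$scale_factor
  stopifnot(f > 0, f <= 1)
  arr <- resizeArray(vol@voxels, f)
  VolumeImage(arr, vol@spacing / f)
}

resizeArray <- function(arr, factor, linear = TRUE) {
  d <- dim(arr)
  cs <- lapply(d, resizeCoords, factor = factor)
  nOut <- vapply(cs, `[[`, integer(1), "n")
  if (any(nOut < 1L)) stop("degenerate output shape")
  A <- diag(3) / factor
  b <- rep((0.5 / factor) - 0.5, 3)
  storage.mode(arr) <- "double"
  cpp_resample_affine(arr, as.integer(nOut), A, b, linear)
}

#' Resize atlas sub-regions into fractional membership volumes
#'
#' Each region's indicator volume is resized independently with trilinear
#' interpolation; the resulting values are the per-voxel occupancy fractions
#' of that region on the PET grid. By linearity the fractions sum to the
#' resized whole-volume indicator, so they partition each interior PET voxel.
#'
#' @param atlas a \code{\linkS4class{LabelAtlas}}.
#' @param spec scale-factor spec from \code{\link{computeScaleFactor}}.
#' @param sparseCutoff fractions at or below this value are zeroed to bound
#'   memory (default 1e-3).
#' @return A \code{\linkS4class{FractionalAtlas}}; the brain mask is the set
#'   of voxels with total fraction > 0.5.
#' @export
resizeSubregions <- function(atlas, spec, sparseCutoff = 1e-3) {
  ids <- sort(setdiff(unique(as.integer(atlas@labels)), 0L))
  if (length(ids) == 0L) stop("atlas has no nonzero region")
  fr <- lapply(ids, function(id) {
    ind <- array(as.double(atlas@labels == id), dim(atlas@labels))
    f <- resizeArray(ind, spec$scale_factor)
    f[f <= sparseCutoff] <- 0
    pmin(pmax(f, 0), 1)
  })
  names(fr) <- as.character(ids)
  tot <- Reduce(`+`, fr)
  ov <- tot > 1
  if (any(ov)) for (i in seq_along(fr)) fr[[i]][ov] <- fr[[i]][ov] / tot[ov]
  mask <- tot > 0.5
  dim(mask) <- dim(tot)
  sp <- atlas@spacing / spec$scale_factor
  new("FractionalAtlas", fractions = fr,
      brainMask = BinaryMask(mask, sp), spacing = sp,
      labelTable = atlas@labelTable[atlas@labelTable$id %in% ids, ,
                                    drop = FALSE])
}

#' Split one atlas region into left/right hemispheres
#'
#' Relabels a region into two new labels at the sagittal midplane of the
#' region's bounding box along the left-right axis (needed when an atlas
#' carries e.g. the cortex as a single bilateral region).
#'
#' @param atlas a \code{\linkS4class{LabelAtlas}}.
#' @param regionId id of the region to split.
#' @param midlineAxis left-right axis index (default 1, the x axis).
#' @return A new \code{LabelAtlas} where \code{regionId} is replaced by two
#'   labels named \code{<name>_left} / \code{<name>_right}.
#' @export
splitRegionHemispheres <- function(atlas, regionId, midlineAxis = 1L) {
  lab <- atlas@labels
  sel <- lab == regionId
  if (!any(sel)) stop("region absent from atlas: ", regionId)
  idx <- which(sel, arr.ind = TRUE)
  ax <- idx[, midlineAxis]
  mid <- (min(ax) + max(ax)) / 2
  leftId <- max(atlas@labelTable$id) + 1L
  rightId <- leftId + 1L
  isLeft <- ax <= mid
  lab[sel] <- ifelse(isLeft, leftId, rightId)
  if (!any(isLeft) || all(isLeft))
    warning("region lies entirely on one side of the midline")
  nm <- atlas@labelTable$name[match(regionId, atlas@labelTable$id)]
  tab <- atlas@labelTable[atlas@labelTable$id != regionId, , drop = FALSE]
  tab <- rbind(tab, data.frame(id = c(leftId, rightId),
                               name = paste0(nm, c("_left", "_right"))))
  LabelAtlas(lab, atlas@spacing, tab)
}
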