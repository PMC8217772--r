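#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib petquant, .registration = TRUE
NULL

#' DynamicImage: a 4-D dynamic PET volume
#'
#' Holds a reconstructed dynamic PET acquisition as a 4-D voxel grid
#' (x, y, z, frame) together with the voxel spacing in micrometres and the
#' frame schedule. Voxel values are treated as activity concentration
#' (Bq/mL) as calibrated by the scanner; no decay correction is applied.
#' The axial (slice) axis is the third spatial dimension, with the caudal
#' direction at increasing z.
#'
#' @slot voxels 4-D numeric array, dims (nx, ny, nz, nframes).
#' @slot spacing numeric(3), per-axis voxel size in micrometres.
#' @slot frameSchedule data.frame with columns \code{start_s}, \code{end_s};
#'   half-open intervals \code{[start, end)} in seconds, sorted and
#'   non-overlapping, one row per frame.
#' @slot meta list, free-form provenance.
#' @export
setClass("DynamicImage",
  representation(voxels = "array", spacing = "numeric",
                 frameSchedule = "data.frame", meta = "list"),
  prototype(meta = list()))

setValidity("DynamicImage", function(object) {
  msgs <- character()
  d <- dim(object@voxels)
  if (length(d) != 4L) msgs <- c(msgs, "voxels must be a 4-D array")
  if (any(d == 0L)) msgs <- c(msgs, "voxel grid must be non-empty")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be three positive values (micrometres)")
  fs <- object@frameSchedule
  if (!all(c("start_s", "end_s") %in% names(fs)))
    msgs <- c(msgs, "frameSchedule needs columns start_s, end_s")
  else {
    if (length(d) == 4L && nrow(fs) != d[4L])
      msgs <- c(msgs, "number of frame intervals must equal the frame dimension")
    if (nrow(fs) > 0 && any(fs$end_s <= fs$start_s))
      msgs <- c(msgs, "frame intervals must have end > start")
    if (nrow(fs) > 1) {
      if (is.unsorted(fs$start_s, strictly = TRUE))
        msgs <- c(msgs, "frame intervals must be sorted")
      if (any(fs$start_s[-1] < fs$end_s[-nrow(fs)]))
        msgs <- c(msgs, "frame intervals must not overlap")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' VolumeImage: a single 3-D intensity volume
#'
#' @slot voxels 3-D numeric array (nx, ny, nz); finite values only.
#' @slot spacing numeric(3), micrometres.
#' @export
setClass("VolumeImage",
  representation(voxels = "array", spacing = "numeric"))

setValidity("VolumeImage", function(object) {
  msgs <- character()
  if (length(dim(object@voxels)) != 3L) msgs <- c(msgs, "voxels must be 3-D")
  if (any(!is.finite(object@voxels))) msgs <- c(msgs, "voxel values must be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be three positive values")
  if (length(msgs)) msgs else TRUE
})

#' BinaryMask: a 3-D boolean volume
#'
#' @slot voxels 3-D logical array.
#' @slot spacing numeric(3), micrometres.
#' @export
setClass("BinaryMask",
  representation(voxels = "array", spacing = "numeric"))

setValidity("BinaryMask", function(object) {
  msgs <- character()
  if (length(dim(object@voxels)) != 3L) msgs <- c(msgs, "voxels must be 3-D")
  if (!is.logical(object@voxels)) msgs <- c(msgs, "voxels must be logical")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be three positive values")
  if (length(msgs)) msgs else TRUE
})

#' LabelAtlas: an integer-labelled anatomical atlas
#'
#' @slot labels 3-D integer array, 0 = background.
#' @slot spacing numeric(3), micrometres.
#' @slot labelTable data.frame with columns \code{id}, \code{name}; every
#'   nonzero label present in the grid must appear in the table.
#' @export
setClass("LabelAtlas",
  representation(labels = "array", spacing = "numeric",
                 labelTable = "data.frame"))

setValidity("LabelAtlas", function(object) {
  msgs <- character()
  if (length(dim(object@labels)) != 3L) msgs <- c(msgs, "labels must be 3-D")
  if (any(object@labels < 0)) msgs <- c(msgs, "labels must be >= 0")
  if (!all(c("id", "name") %in% names(object@labelTable)))
    msgs <- c(msgs, "labelTable needs columns id, name")
  else {
    present <- setdiff(unique(as.integer(object@labels)), 0L)
    if (!all(present %in% object@labelTable$id))
      msgs <- c(msgs, "every nonzero label in the grid must appear in labelTable")
  }
  if (length(msgs)) msgs else TRUE
})

#' FractionalAtlas: atlas labels on the PET grid with per-voxel fractions
#'
#' Each atlas sub-region is carried as a volume of fractional occupancy on
#' the coarser PET grid; at voxels inside the resized whole-volume support
#' the fractions sum to one.
#'
#' @slot fractions named list of 3-D numeric arrays (one per region id,
#'   names are region ids as character), values in [0, 1].
#' @slot brainMask \code{BinaryMask}, the union support (total fraction > 0.5).
#' @slot spacing numeric(3), micrometres of the PET grid.
#' @slot labelTable data.frame (id, name).
#' @export
setClass("FractionalAtlas",
  representation(fractions = "list", brainMask = "BinaryMask",
                 spacing = "numeric", labelTable = "data.frame"))

setValidity("FractionalAtlas", function(object) {
  msgs <- character()
  if (length(object@fractions) == 0) msgs <- c(msgs, "no region fractions")
  rng <- range(vapply(object@fractions, function(f) range(f),
                      numeric(2)))
  if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
    msgs <- c(msgs, "fractions must lie in [0, 1]")
  tot <- Reduce(`+`, object@fractions)
  if (max(tot) > 1 + 1e-6)
    msgs <- c(msgs, "total fraction must not exceed 1")
  if (length(msgs)) msgs else TRUE
})

#' Transform: a parametric spatial mapping
#'
#' A pull-back map from the fixed frame's voxel grid into the moving frame:
#' resampling an image with the transform evaluates the image at
#' \code{A p + b} (rigid/affine) or \code{p + u(p)} (deformable) for each
#' fixed-space voxel p (0-based voxel units).
#'
#' @slot kind "rigid", "affine" or "deformable".
#' @slot parameters list; for rigid/affine: \code{A} (3x3), \code{b}
#'   (length 3), and for rigid additionally \code{angles_deg},
#'   \code{translation_vox}; for deformable: \code{ux,uy,uz} displacement
#'   arrays in voxel units.
#' @slot fixedFrame,movingFrame character frame identifiers.
#' @export
setClass("Transform",
  representation(kind = "character", parameters = "list",
                 fixedFrame = "character", movingFrame = "character"))

setValidity("Transform", function(object) {
  msgs <- character()
  if (!object@kind %in% c("rigid", "affine", "deformable"))
    msgs <- c(msgs, "kind must be rigid, affine or deformable")
  if (object@kind == "rigid") {
    A <- object@parameters$A
    if (!is.null(A)) {
      if (max(abs(crossprod(A) - diag(3))) > 1e-6)
        msgs <- c(msgs, "rigid linear part must be orthonormal")
      if (abs(det(A) - 1) > 1e-6)
        msgs <- c(msgs, "rigid linear part must have det +1")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' TransformChain: an ordered list of Transforms
#'
#' Step k maps from step k-1's fixed frame onward: adjacent steps must have
#' \code{movingFrame(step k) == fixedFrame(step k-1)}. Applying a chain
#' resamples an image living in the first step's moving frame into the last
#' step's fixed frame in a single interpolation pass.
#'
#' @slot transforms list of \code{Transform}.
#' @export
setClass("TransformChain", representation(transforms = "list"))

setValidity("TransformChain", function(object) {
  tr <- object@transforms
  if (length(tr) > 1) {
    for (k in 2:length(tr)) {
      if (!identical(tr[[k]]@movingFrame, tr[[k - 1]]@fixedFrame))
        return(sprintf("chain step %d moving frame does not match step %d fixed frame",
                       k, k - 1))
    }
  }
  TRUE
})

#' Template: an averaged control-group PET image with its VOI
#'
#' @slot image \code{VolumeImage}, voxel-wise mean of the centred reference
#'   and the aligned members.
#' @slot voiMask \code{BinaryMask}.
#' @slot referenceId character identifier of the reference member.
#' @slot memberTransforms named list of \code{TransformChain}, one per member.
#' @export
setClass("Template",
  representation(image = "VolumeImage", voiMask = "BinaryMask",
                 referenceId = "character", memberTransforms = "list"))

setValidity("Template", function(object) {
  msgs <- character()
  if (!any(object@voiMask@voxels)) msgs <- c(msgs, "voiMask must be nonempty")
  if (length(object@memberTransforms) < 1)
    msgs <- c(msgs, "template needs at least one member")
  if (length(msgs)) msgs else TRUE
})

#' QuantResult: per-region semi-quantitative uptake values
#'
#' Tidy table of the three semi-quantitative parameters per animal, state,
#' region and time interval: normalized activity A_N (dimensionless),
#' standardized uptake value SUV (g/mL) and uptake ratio UR (dimensionless).
#'
#' @slot table data.frame with columns animal_id, group, state, region,
#'   interval, A_N, SUV, UR.
#' @slot referenceRegion character: the region id used as UR denominator, or
#'   \code{"whole_voi"}.
#' @export
setClass("QuantResult",
  representation(table = "data.frame", referenceRegion = "character"))

setValidity("QuantResult", function(object) {
  need <- c("animal_id", "group", "state", "region", "interval",
            "A_N", "SUV", "UR")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  vals <- unlist(object@table[, c("A_N", "SUV", "UR")])
  if (any(!is.finite(vals)) || any(vals < 0))
    return("A_N, SUV, UR must be finite and >= 0")
  TRUE
})
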