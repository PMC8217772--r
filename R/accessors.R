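#' Accessors for image objects
#'
#' \code{voxels()} returns the voxel array, \code{spacing()} the per-axis
#' voxel size in micrometres, \code{frameSchedule()} the frame interval
#' table of a \code{DynamicImage}, and \code{nFrames()} its frame count.
#'
#' @param object a \code{DynamicImage}, \code{VolumeImage}, \code{BinaryMask},
#'   \code{LabelAtlas} or \code{FractionalAtlas}.
#' @return See description.
#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("frameSchedule", function(object) standardGeneric("frameSchedule"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
setMethod("voxels", "DynamicImage", function(object) object@voxels)
#' @rdname accessors
setMethod("voxels", "VolumeImage", function(object) object@voxels)
#' @rdname accessors
setMethod("voxels", "BinaryMask", function(object) object@voxels)
#' @rdname accessors
setMethod("voxels", "LabelAtlas", function(object) object@labels)

#' @rdname accessors
setMethod("spacing", "DynamicImage", function(object) object@spacing)
#' @rdname accessors
setMethod("spacing", "VolumeImage", function(object) object@spacing)
#' @rdname accessors
setMethod("spacing", "BinaryMask", function(object) object@spacing)
#' @rdname accessors
setMethod("spacing", "LabelAtlas", function(object) object@spacing)
#' @rdname accessors
setMethod("spacing", "FractionalAtlas", function(object) object@spacing)

#' @rdname accessors
setMethod("frameSchedule", "DynamicImage", function(object) object@frameSchedule)
#' @rdname accessors
setMethod("nFrames", "DynamicImage", function(object) dim(object@voxels)[4L])

#' Label table of an atlas
#' @param object a \code{LabelAtlas} or \code{FractionalAtlas}.
#' @return data.frame with columns id, name.
#' @rdname labelTable
#' @export
setGeneric("labelTable", function(object) standardGeneric("labelTable"))
#' @rdname labelTable
setMethod("labelTable", "LabelAtlas", function(object) object@labelTable)
#' @rdname labelTable
setMethod("labelTable", "FractionalAtlas", function(object) object@labelTable)

#' Region fraction volumes of a FractionalAtlas
#' @param object a \code{FractionalAtlas}.
#' @param region optional region id; if missing, the full named list.
#' @return 3-D array of fractions, or the list of all of them.
#' @export
setGeneric("regionFractions",
           function(object, region) standardGeneric("regionFractions"))
#' @rdname regionFractions
setMethod("regionFractions", "FractionalAtlas", function(object, region) {
  if (missing(region)) return(object@fractions)
  key <- as.character(region)
  if (is.null(object@fractions[[key]]))
    stop("region not present in atlas: ", key)
  object@fractions[[key]]
})

#' Brain support mask of a FractionalAtlas
#' @param object a \code{FractionalAtlas}.
#' @return \code{BinaryMask}.
#' @export
setGeneric("brainMask", function(object) standardGeneric("brainMask"))
#' @rdname brainMask
setMethod("brainMask", "FractionalAtlas", function(object) object@brainMask)

#' Quantification table of a QuantResult
#' @param object a \code{QuantResult}.
#' @return data.frame in tidy layout.
#' @export
setGeneric("quantTable", function(object) standardGeneric("quantTable"))
#' @rdname quantTable
setMethod("quantTable", "QuantResult", function(object) object@table)

setMethod("show", "DynamicImage", function(object) {
  d <- dim(object@voxels)
  cat("DynamicImage:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "frames\n")
  cat("  spacing (um):", paste(round(object@spacing, 1), collapse = " x "), "\n")
  fs <- object@frameSchedule
  cat("  time span (s): [", fs$start_s[1], ",", fs$end_s[nrow(fs)], ")\n")
})

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@voxels)
  cat("VolumeImage:", paste(d, collapse = " x "),
      sprintf("voxels, range [%.3g, %.3g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "BinaryMask", function(object) {
  cat("BinaryMask:", paste(dim(object@voxels), collapse = " x "),
      "voxels,", sum(object@voxels), "foreground\n")
})

setMethod("show", "LabelAtlas", function(object) {
  cat("LabelAtlas:", paste(dim(object@labels), collapse = " x "), "voxels,",
      nrow(object@labelTable), "regions\n")
})

setMethod("show", "FractionalAtlas", function(object) {
  cat("FractionalAtlas:", length(object@fractions), "regions on a",
      paste(dim(object@brainMask@voxels), collapse = " x "), "grid\n")
})

setMethod("show", "Transform", function(object) {
  cat("Transform (", object@kind, "): ", object@movingFrame, " -> ",
      object@fixedFrame, "\n", sep = "")
})

setMethod("show", "TransformChain", function(object) {
  cat("TransformChain with", length(object@transforms), "step(s)\n")
  for (tr in object@transforms)
    cat("  ", tr@kind, ": ", tr@movingFrame, " -> ", tr@fixedFrame, "\n",
        sep = "")
})

setMethod("show", "Template", function(object) {
  cat("Template from", length(object@memberTransforms), "member(s);",
      "reference:", object@referenceId, "\n")
  cat("  VOI voxels:", sum(object@voiMask@voxels), "\n")
})

setMethod("show", "QuantResult", function(object) {
  cat("QuantResult:", nrow(object@table), "rows;",
      length(unique(object@table$region)), "regions;",
      "UR reference:", object@referenceRegion, "\n")
})
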