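# NIfTI-1 / ANALYZE 7.5 import and export (module: image_io_preprocess).

#' Read a PET volume from NIfTI or ANALYZE
#'
#' Reads a 3-D or 4-D volume; 3-D inputs are promoted to a single-frame
#' \code{\linkS4class{DynamicImage}}. Voxel spacing is taken from the header
#' and converted to micrometres. The frame schedule is taken from the time
#' step in the header (one interval per frame) unless \code{frameSchedule}
#' overrides it.
#'
#' @param path path to a \code{.nii}, \code{.nii.gz} or ANALYZE
#'   \code{.hdr}/\code{.img} pair.
#' @param frameSchedule optional data.frame (start_s, end_s) overriding the
#'   header-derived schedule.
#' @return A \code{\linkS4class{DynamicImage}}.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(VolumeImage(array(1, c(4, 4, 4)), c(1000, 1000, 1000)), f)
#' img <- readVolume(f)
#' nFrames(img)
#' @export
readVolume <- function(path, frameSchedule = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  nii <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("unreadable image file: ", path,
                                           " (", conditionMessage(e), ")"))
  arr <- as.array(nii)
  attributes(arr) <- list(dim = dim(arr)) # strip niftiImage class/attrs
  nd <- length(dim(arr))
  if (nd < 3L) stop("image must have at least 3 dimensions")
  if (nd > 4L) stop("images with more than 4 dimensions are not supported")
  pd <- RNifti::pixdim(nii)
  un <- tryCatch(RNifti::pixunits(nii), error = function(e) "mm")
  mult <- if (any(un == "m")) 1e6 else if (any(un == "um")) 1 else 1e3
  sp <- abs(pd[1:3]) * mult
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid voxel spacing in header")
  if (nd == 3L) dim(arr) <- c(dim(arr), 1L)
  nframes <- dim(arr)[4L]
  if (is.null(frameSchedule)) {
    dt <- if (length(pd) >= 4L && is.finite(pd[4L]) && pd[4L] > 0) pd[4L] else 1
    frameSchedule <- frameTable((seq_len(nframes) - 1) * dt,
                                seq_len(nframes) * dt)
  }
  storage.mode(arr) <- "double"
  DynamicImage(arr, sp, frameSchedule, meta = list(path = path))
}

#' Write a volume or mask to NIfTI
#'
#' Masks are written as uint8; spacing is written in millimetres.
#'
#' @param x a \code{VolumeImage}, \code{BinaryMask} or \code{DynamicImage}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(x, path) {
  if (is(x, "BinaryMask")) {
    arr <- array(as.integer(x@voxels), dim(x@voxels))
    storage.mode(arr) <- "integer"
    dt <- "uint8"
  } else if (is(x, "VolumeImage") || is(x, "DynamicImage")) {
    arr <- x@voxels
    storage.mode(arr) <- "double"
    dt <- "double"
  } else stop("unsupported object of class ", class(x))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(x@spacing / 1e3, rep(1, length(dim(arr)) - 3L))
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read an atlas label table
#'
#' Two-column tab-separated file: integer region id, region name.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns id, name.
#' @export
readLabelTable <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("label table needs two columns (id, name)")
  data.frame(id = as.integer(tab[[1]]), name = as.character(tab[[2]]))
}

#' Read a label atlas volume plus its label table
#'
#' @param imagePath NIfTI/ANALYZE path of the integer label volume.
#' @param tablePath path of the tab-separated label table.
#' @return A \code{\linkS4class{LabelAtlas}}.
#' @export
readLabelAtlas <- function(imagePath, tablePath) {
  img <- readVolume(imagePath)
  lab <- img@voxels[, , , 1L]
  LabelAtlas(lab, img@spacing, readLabelTable(tablePath))
}
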