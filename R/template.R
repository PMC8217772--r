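# Control-group PET template: reference selection by VOI orientation,
# centring, deformable averaging, and template-VOI segmentation including
# the intensity-inverted variant for target-selective tracers
# (module: template_builder).

#' Principal-axis orientation of a VOI mask
#'
#' Eigendecomposition of the second-moment (inertia) matrix of the mask.
#' Exploiting the ellipsoidal brain shape and the animal's positioning, the
#' longest principal axis is assigned to z, the middle to x and the shortest
#' to y; each angle is the angle between the assigned eigenvector and its
#' coordinate axis, in [0, 90] degrees.
#'
#' @param mask a \code{BinaryMask} (or logical array), nonempty and with
#'   three distinct principal axis lengths.
#' @return list with \code{theta_z}, \code{theta_x}, \code{theta_y}
#'   (degrees), \code{axis_lengths} (sorted long to short, voxel units) and
#'   \code{centroid} (1-based voxel coordinates).
#' @export
voiOrientation <- function(mask) {
  m <- if (is(mask, "BinaryMask")) mask@voxels else mask
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  ctr <- colMeans(idx)
  X <- sweep(idx, 2, ctr)
  C <- crossprod(X) / nrow(X)
  eig <- eigen(C, symmetric = TRUE)
  len <- 2 * sqrt(pmax(eig$values, 0)) # axis half-length scale, long to short
  if (any(diff(len) > -1e-6 * max(len)))
    stop("isotropic mask: principal axes are degenerate")
  vecs <- eig$vectors # columns ordered by decreasing eigenvalue
  angleTo <- function(v, axis) {
    u <- numeric(3); u[axis] <- 1
    acos(pmin(1, abs(sum(v * u)) / sqrt(sum(v^2)))) * 180 / pi
  }
  list(theta_z = angleTo(vecs[, 1], 3L),
       theta_x = angleTo(vecs[, 2], 1L),
       theta_y = angleTo(vecs[, 3], 2L),
       axis_lengths = len, centroid = ctr)
}

#' Select the control-group reference image by VOI orientation
#'
#' Returns the index of the mask whose VOI is best aligned with the
#' coordinate axes: the argmin of \code{theta_z + theta_x + theta_y}, ties
#' broken by smallest \code{theta_z}, then lowest index.
#'
#' @param masks list of \code{BinaryMask}.
#' @return integer index (1-based).
#' @export
selectReference <- function(masks) {
  if (length(masks) < 1L) stop("need at least one mask")
  ang <- lapply(masks, voiOrientation)
  tot <- vapply(ang, function(a) a$theta_z + a$theta_x + a$theta_y, numeric(1))
  tz <- vapply(ang, `[[`, numeric(1), "theta_z")
  ord <- order(tot, tz, seq_along(masks))
  ord[1L]
}

#' Centre a volume on its VOI centroid
#'
#' Integer-voxel translation moving the VOI centroid to the grid centre
#' (nearest-integer shift, no interpolation); content shifted outside the
#' grid is cropped with a warning.
#'
#' @param img a \code{VolumeImage}.
#' @param mask the VOI \code{BinaryMask} (same grid).
#' @return \code{list(image = VolumeImage, mask = BinaryMask,
#'   shift = integer(3))}.
#' @export
centerVoi <- function(img, mask) {
  assertVolume(img)
  m <- mask@voxels
  ctr <- maskCentroid(m)
  d <- dim(img@voxels)
  target <- (d + 1) / 2
  shift <- round(target - ctr)
  if (all(shift == 0))
    return(list(image = img, mask = mask, shift = as.integer(shift)))
  shiftArr <- function(a, fill) {
    out <- array(fill, d)
    src <- lapply(1:3, function(k) seq_len(d[k]) - shift[k])
    ok <- lapply(1:3, function(k) src[[k]] >= 1 & src[[k]] <= d[k])
    dst <- lapply(1:3, function(k) which(ok[[k]]))
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
    lost <- sum(a != fill) - sum(out != fill)
    if (lost > 0)
      warning("content cropped at the grid edge while centring (",
              lost, " voxels)")
    out
  }
  list(image = VolumeImage(shiftArr(img@voxels, 0), img@spacing),
       mask = BinaryMask(shiftArr(m, FALSE), mask@spacing),
       shift = as.integer(shift))
}

#' Build the PET template from the control group
#'
#' The reference image is centred on its VOI; every other control is
#' deformably registered to it (correlation-coefficient similarity,
#' iteration cap and convergence tolerance as defaults); the template image
#' is the voxel-wise mean of the centred reference and all aligned members,
#' and the member transform chains are retained for reuse.
#'
#' @param controls list of summed \code{VolumeImage} (control group).
#' @param masks list of their VOI \code{BinaryMask}s.
#' @param reference index of the reference member (from
#'   \code{\link{selectReference}}).
#' @param ids optional character ids, default \code{"control_<i>"}.
#' @param iterations deformable iteration cap (default 1000).
#' @param tol convergence tolerance on the similarity (default 1e-8).
#' @return A \code{\linkS4class{Template}}.
#' @export
buildTemplate <- function(controls, masks, reference, ids = NULL,
                          iterations = 1000L, tol = 1e-8) {
  n <- length(controls)
  stopifnot(n >= 1L, reference >= 1L, reference <= n)
  if (is.null(ids)) ids <- paste0("control_", seq_len(n))
  cen <- centerVoi(controls[[reference]], masks[[reference]])
  refImg <- cen$image
  aligned <- vector("list", n)
  chains <- vector("list", n)
  names(chains) <- ids
  shiftTr <- new("Transform", kind = "rigid",
                 parameters = list(A = diag(3), b = as.numeric(-cen$shift),
                                   angles_deg = c(0, 0, 0),
                                   translation_vox = as.numeric(cen$shift)),
                 fixedFrame = "template", movingFrame = ids[reference])
  for (i in seq_len(n)) {
    if (i == reference) {
      aligned[[i]] <- refImg@voxels
      chains[[i]] <- new("TransformChain", transforms = list(shiftTr))
      next
    }
    reg <- deformableRegister(controls[[i]], refImg, iterations = iterations,
                              tol = tol,
                              movingFrame = ids[i], fixedFrame = "template")
    if (!is.finite(reg$similarity))
      stop("deformable registration failed for member ", ids[i])
    aligned[[i]] <- reg$resampled@voxels
    chains[[i]] <- new("TransformChain", transforms = list(reg$transform))
  }
  meanImg <- Reduce(`+`, aligned) / n
  tmplImg <- VolumeImage(meanImg, refImg@spacing)
  new("Template", image = tmplImg, voiMask = cen$mask,
      referenceId = ids[reference], memberTransforms = chains)
}

#' Segment the template VOI by intensity inversion
#'
#' For target-selective tracers the template VOI holds mostly low uptake
#' with a bright focal target. The template is cropped to its content
#' bounding cuboid (valid because the reference was centred), voxels
#' brighter than half the maximum are excluded, the remainder is
#' contrast-stretched to [0, 1] and inverted so "healthy tissue" becomes
#' bright; the Otsu-thresholded gradient-magnitude shell of the inverted
#' volume acts as a boundary set, and a seed at the grid centre is grown by
#' iterative one-voxel dilation without crossing boundary voxels until
#' convergence. The grown mask is the VOI.
#'
#' @param templateImg \code{VolumeImage}: template of a target-selective
#'   study.
#' @return A \code{BinaryMask} on the template grid.
#' @export
segmentTemplateVoiInverted <- function(templateImg) {
  assertVolume(templateImg, "templateImg")
  v <- templateImg@voxels
  mx <- max(v)
  if (mx <= 0) stop("template image is empty")
  nz <- which(v > 0, arr.ind = TRUE)
  lo <- apply(nz, 2, min); hi <- apply(nz, 2, max)
  crop <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  keep <- crop <= mx / 2 & crop > 0
  if (!any(keep) || length(unique(crop[keep])) < 2L)
    stop("no intensity variation remains after exclusion")
  inv <- array(0, dim(crop))
  r <- range(crop[keep])
  if (r[2] <= r[1]) stop("no intensity variation remains after exclusion")
  inv[keep] <- 1 - (crop[keep] - r[1]) / (r[2] - r[1])
  # gradient magnitude (central differences) of the inverted volume
  g <- gradientMagnitude(inv)
  # cap the Otsu level at half the maximum gradient: on near-piecewise-
  # constant volumes the gradient histogram concentrates on a few interface
  # magnitudes and plain Otsu can cut away part of the interface shell
  gthr <- min(otsuThresholds(g[g > 0], 1L), 0.5 * max(g))
  boundary <- g > gthr
  dim(boundary) <- dim(inv)
  # close diagonal gaps in the gradient shell so the growth cannot leak
  boundary <- morph3(boundary, "dilate", connectivity = 6L)
  valid <- keep & !boundary
  dim(valid) <- dim(inv)
  seed <- round((dim(inv) + 1) / 2)
  if (!valid[seed[1], seed[2], seed[3]]) {
    cand <- which(valid, arr.ind = TRUE)
    if (nrow(cand) == 0) stop("no growable voxels inside the boundary")
    dd <- rowSums(sweep(cand, 2, seed)^2)
    seed <- cand[which.min(dd), ]
  }
  seedMask <- array(FALSE, dim(inv))
  seedMask[seed[1], seed[2], seed[3]] <- TRUE
  lab <- cpp_grow_markers(valid, array(as.integer(seedMask), dim(inv)))
  grown <- lab == 1L
  dim(grown) <- dim(inv)
  # recover the band consumed by the (dilated) boundary shell
  grown <- morph3(grown, "dilate") & keep
  grown <- morph3(grown, "dilate", connectivity = 6L) & keep
  out <- array(FALSE, dim(v))
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- grown
  BinaryMask(out, templateImg@spacing)
}

gradientMagnitude <- function(a) {
  d <- dim(a)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  if (d[1] > 2) gx[2:(d[1]-1), , ] <- (a[3:d[1], , ] - a[1:(d[1]-2), , ]) / 2
  if (d[2] > 2) gy[, 2:(d[2]-1), ] <- (a[, 3:d[2], ] - a[, 1:(d[2]-2), ]) / 2
  if (d[3] > 2) gz[, , 2:(d[3]-1)] <- (a[, , 3:d[3]] - a[, , 1:(d[3]-2)]) / 2
  sqrt(gx^2 + gy^2 + gz^2)
}
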