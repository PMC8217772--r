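# Rigid / affine / deformable registration, transform reuse, auxiliary
# alignment structures and similarity reporting (module:
# registration_alignment). The backend is native: parametric transforms
# optimised over an intensity metric with the Rcpp trilinear resampler;
# deformable refinement is a dense demons scheme with Gaussian
# regularisation whose convergence is monitored on the correlation
# coefficient.

# ---- parametric maps ------------------------------------------------------

# pull-back map for content rotated by `angles` (deg), scaled by exp(logScale),
# sheared, then translated by `trans` (voxels): sample coordinate of fixed
# voxel p is A (p - cFix - trans) + cMov
paramsToMap <- function(angles, trans, logScale = c(0, 0, 0),
                        shear = c(0, 0, 0), dimFixed, dimMoving) {
  R <- rotationMatrix3(angles)
  S <- diag(exp(logScale))
  Sh <- matrix(c(1, shear[1], shear[2],
                 0, 1, shear[3],
                 0, 0, 1), 3, 3, byrow = TRUE)
  L <- R %*% S %*% Sh
  A <- solve(L)
  cFix <- (dimFixed - 1) / 2
  cMov <- (dimMoving - 1) / 2
  b <- as.numeric(cMov - A %*% (cFix + trans))
  list(A = A, b = b)
}

resampleByMap <- function(movArr, dimFixed, map, linear = TRUE) {
  storage.mode(movArr) <- "double"
  cpp_resample_affine(movArr, as.integer(dimFixed), map$A, map$b, linear)
}

metricValue <- function(res, fix, metric) {
  if (metric == "mean_squares") return(mean((res - fix)^2))
  if (metric == "correlation") {
    cc <- suppressWarnings(stats::cor(as.vector(res), as.vector(fix)))
    return(if (is.na(cc)) 1 else 1 - cc)
  }
  if (metric == "mutual_information") {
    jh <- jointHistogramStats(res, fix, bins = 64L)
    return(-jh$mutual_information)
  }
  stop("unknown metric: ", metric)
}

registerParametric <- function(moving, fixed, kind, metric, iterations, tol,
                               movingFrame, fixedFrame) {
  assertVolume(moving, "moving"); assertVolume(fixed, "fixed")
  movN <- normalize01(moving@voxels)
  fixN <- normalize01(fixed@voxels)
  dM <- dim(movN); dF <- dim(fixN)
  # translation initialisation from intensity centroids
  wcent <- function(a) {
    s <- sum(a)
    if (s <= 0) return((dim(a) + 1) / 2)
    idx <- 1:3
    vapply(idx, function(k) {
      sum(apply(a, k, sum) * seq_len(dim(a)[k])) / s
    }, numeric(1))
  }
  t0 <- (wcent(fixN) - (dF + 1) / 2) - (wcent(movN) - (dM + 1) / 2)
  nPar <- if (kind == "rigid") 6L else 12L
  p0 <- c(0, 0, 0, t0, if (kind == "affine") rep(0, 6))
  objective <- function(p) {
    map <- paramsToMap(p[1:3], p[4:6],
                       if (nPar == 12L) p[7:9] else c(0, 0, 0),
                       if (nPar == 12L) p[10:12] else c(0, 0, 0), dF, dM)
    res <- resampleByMap(movN, dF, map)
    metricValue(res, fixN, metric)
  }
  ctl <- list(maxit = min(iterations, 5000L),
              reltol = max(tol, 1e-12),
              parscale = c(rep(2, 3), rep(1, 3),
                           if (nPar == 12L) rep(0.05, 6)))
  fit <- stats::optim(p0, objective, method = "Nelder-Mead", control = ctl)
  fit2 <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                       control = ctl)
  if (fit2$value <= fit$value) fit <- fit2
  if (!is.finite(fit$value))
    stop("registration did not converge; last similarity value: ", fit$value)
  p <- fit$par
  map <- paramsToMap(p[1:3], p[4:6],
                     if (nPar == 12L) p[7:9] else c(0, 0, 0),
                     if (nPar == 12L) p[10:12] else c(0, 0, 0), dF, dM)
  params <- list(A = map$A, b = map$b, angles_deg = p[1:3],
                 translation_vox = p[4:6], metric = metric,
                 final_value = fit$value)
  if (kind == "affine") {
    params$log_scale <- p[7:9]
    params$shear <- p[10:12]
  }
  new("Transform", kind = kind, parameters = params,
      fixedFrame = fixedFrame, movingFrame = movingFrame)
}

#' Rigid intensity-based registration
#'
#' Estimates rotation plus translation (no scaling) of \code{moving} onto
#' \code{fixed} by maximising an intensity similarity on min-max normalised
#' copies; the returned transform resamples the original (unnormalised)
#' data. Defaults follow the within-subject alignment settings (iteration
#' cap 2000, tolerance 1e-21, clamped to machine precision in the
#' optimiser).
#'
#' @param moving,fixed \code{VolumeImage}s with overlapping content.
#' @param metric \code{"mean_squares"} (default, mono-modal),
#'   \code{"correlation"} or \code{"mutual_information"}.
#' @param iterations iteration cap.
#' @param tol convergence tolerance.
#' @param movingFrame,fixedFrame frame identifiers.
#' @return A rigid \code{\linkS4class{Transform}}.
#' @export
rigidRegister <- function(moving, fixed, metric = "mean_squares",
                          iterations = 2000L, tol = 1e-21,
                          movingFrame = "moving", fixedFrame = "fixed") {
  registerParametric(moving, fixed, "rigid", metric, iterations, tol,
                     movingFrame, fixedFrame)
}

#' Affine intensity-based registration
#'
#' As \code{\link{rigidRegister}} with full affine parameters (rotation,
#' translation, per-axis scale, shear).
#'
#' @inheritParams rigidRegister
#' @param metric \code{"correlation"} (default) or
#'   \code{"mutual_information"} for cross-modality pairs.
#' @return An affine \code{\linkS4class{Transform}}.
#' @export
affineRegister <- function(moving, fixed,
                           metric = c("correlation", "mutual_information",
                                      "mean_squares"),
                           iterations = 2000L, tol = 1e-15,
                           movingFrame = "moving", fixedFrame = "fixed") {
  metric <- match.arg(metric)
  registerParametric(moving, fixed, "affine", metric, iterations, tol,
                     movingFrame, fixedFrame)
}

#' Deformable registration (demons refinement over a rigid initialisation)
#'
#' Rigid pre-alignment followed by dense demons refinement with Gaussian
#' field regularisation; convergence is declared when the correlation
#' coefficient between the warped moving image and the fixed image changes
#' by less than \code{tol} (default 1e-8, iteration cap 1000). The combined
#' map is returned as one deformable \code{Transform} holding the total
#' displacement field.
#'
#' @param moving,fixed \code{VolumeImage}s (same grid).
#' @param iterations demons iteration cap.
#' @param tol convergence tolerance on the correlation coefficient.
#' @param sigmaField Gaussian regularisation sigma in voxels (default 1.5).
#' @param rigidInit run a rigid pre-alignment first (default TRUE).
#' @param movingFrame,fixedFrame frame identifiers.
#' @return \code{list(transform, resampled, similarity)} where
#'   \code{similarity} is the final correlation coefficient.
#' @export
deformableRegister <- function(moving, fixed, iterations = 1000L, tol = 1e-8,
                               sigmaField = 1.5, rigidInit = TRUE,
                               movingFrame = "moving", fixedFrame = "fixed") {
  assertVolume(moving, "moving"); assertVolume(fixed, "fixed")
  dF <- dim(fixed@voxels)
  movN <- normalize01(moving@voxels)
  fixN <- normalize01(fixed@voxels)
  if (rigidInit) {
    rig <- rigidRegister(moving, fixed, movingFrame = movingFrame,
                         fixedFrame = fixedFrame)
    A0 <- rig@parameters$A; b0 <- rig@parameters$b
    movInit <- resampleByMap(movN, dF, list(A = A0, b = b0))
  } else {
    A0 <- diag(3); b0 <- rep(0, 3)
    movInit <- resampleByMap(movN, dF, list(A = A0, b = b0))
  }
  dm <- cpp_demons(fixN, movInit, as.integer(iterations), tol, sigmaField,
                   2.0)
  if (!is.finite(dm$cc))
    stop("deformable registration failed (similarity is NaN)")
  # total map: p -> A0 (p + u(p)) + b0
  d <- dF
  grid <- gridCoords(d)
  px <- grid$x + dm$ux; py <- grid$y + dm$uy; pz <- grid$z + dm$uz
  U <- list(
    ux = array(A0[1,1]*px + A0[1,2]*py + A0[1,3]*pz + b0[1] - grid$x, d),
    uy = array(A0[2,1]*px + A0[2,2]*py + A0[2,3]*pz + b0[2] - grid$y, d),
    uz = array(A0[3,1]*px + A0[3,2]*py + A0[3,3]*pz + b0[3] - grid$z, d))
  tr <- new("Transform", kind = "deformable",
            parameters = list(ux = U$ux, uy = U$uy, uz = U$uz,
                              similarity = dm$cc,
                              iterations = dm$iterations),
            fixedFrame = fixedFrame, movingFrame = movingFrame)
  res <- applyTransformToArray(moving@voxels, list(tr), dF)
  list(transform = tr,
       resampled = VolumeImage(res, fixed@spacing),
       similarity = dm$cc)
}

gridCoords <- function(d) {
  list(x = array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), d),
       y = array(rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]), d),
       z = array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), d))
}

# map 0-based fixed-space coordinates through one transform (pull-back)
mapCoords <- function(tr, X, Y, Z) {
  if (tr@kind %in% c("rigid", "affine")) {
    A <- tr@parameters$A; b <- tr@parameters$b
    list(x = A[1,1]*X + A[1,2]*Y + A[1,3]*Z + b[1],
         y = A[2,1]*X + A[2,2]*Y + A[2,3]*Z + b[2],
         z = A[3,1]*X + A[3,2]*Y + A[3,3]*Z + b[3])
  } else {
    ux <- cpp_sample_at(tr@parameters$ux, X, Y, Z, TRUE)
    uy <- cpp_sample_at(tr@parameters$uy, X, Y, Z, TRUE)
    uz <- cpp_sample_at(tr@parameters$uz, X, Y, Z, TRUE)
    list(x = X + ux, y = Y + uy, z = Z + uz)
  }
}

applyTransformToArray <- function(arr, transforms, outDim) {
  g <- gridCoords(outDim)
  X <- as.numeric(g$x); Y <- as.numeric(g$y); Z <- as.numeric(g$z)
  for (k in rev(seq_along(transforms))) {
    m <- mapCoords(transforms[[k]], X, Y, Z)
    X <- m$x; Y <- m$y; Z <- m$z
  }
  storage.mode(arr) <- "double"
  out <- cpp_sample_at(arr, X, Y, Z, TRUE)
  array(out, outDim)
}

#' Apply a transform chain to an image
#'
#' Coordinates are composed through the whole chain and the source image is
#' sampled in a single trilinear interpolation pass; all frames of a
#' dynamic image receive the identical spatial transform.
#'
#' @param img a \code{VolumeImage} or \code{DynamicImage}.
#' @param chain a \code{TransformChain}, a \code{Transform}, or a list of
#'   \code{Transform}s; an empty chain is the identity.
#' @param outDim optional output grid dims (default: input dims).
#' @param outSpacing optional output spacing.
#' @return An object of the same class as \code{img}.
#' @export
applyTransform <- function(img, chain, outDim = NULL, outSpacing = NULL) {
  transforms <- if (is(chain, "TransformChain")) chain@transforms
                else if (is(chain, "Transform")) list(chain)
                else chain
  if (is(img, "VolumeImage")) {
    d <- if (is.null(outDim)) dim(img@voxels) else outDim
    if (length(transforms) == 0 && identical(d, dim(img@voxels)))
      return(img)
    out <- applyTransformToArray(img@voxels, transforms, d)
    return(VolumeImage(out, if (is.null(outSpacing)) img@spacing
                            else outSpacing))
  }
  if (is(img, "DynamicImage")) {
    d4 <- dim(img@voxels)
    d <- if (is.null(outDim)) d4[1:3] else outDim
    out <- array(0, c(d, d4[4]))
    for (f in seq_len(d4[4]))
      out[, , , f] <- applyTransformToArray(img@voxels[, , , f],
                                            transforms, d)
    return(DynamicImage(out, if (is.null(outSpacing)) img@spacing
                             else outSpacing,
                        img@frameSchedule, img@meta))
  }
  stop("unsupported image class: ", class(img))
}

#' Invert a rigid or affine transform
#' @param tr a rigid or affine \code{Transform}.
#' @return The inverse \code{Transform} (frames swapped).
#' @export
invertTransform <- function(tr) {
  if (!tr@kind %in% c("rigid", "affine"))
    stop("only rigid/affine transforms can be inverted in closed form")
  A <- tr@parameters$A; b <- tr@parameters$b
  Ai <- solve(A)
  new("Transform", kind = tr@kind,
      parameters = list(A = Ai, b = as.numeric(-Ai %*% b)),
      fixedFrame = tr@movingFrame, movingFrame = tr@fixedFrame)
}

# ---- auxiliary structures -------------------------------------------------

#' Auxiliary alignment image for metabolic tracers
#'
#' The metabolic VOI reduction truncated after the adaptive volume
#' threshold: the caudal-third-dropped image masked to all voxels above the
#' adapted threshold. This keeps the VOI plus connected high-uptake
#' structures (notably the Harderian glands), which stabilise rigid
#' within-subject alignment.
#'
#' @param img summed \code{VolumeImage}.
#' @param atlasMask resized atlas support (\code{BinaryMask} or logical
#'   array), used only for its voxel count.
#' @return A \code{VolumeImage}.
#' @export
buildAuxMetabolic <- function(img, atlasMask) {
  assertVolume(img)
  atl <- if (is(atlasMask, "BinaryMask")) atlasMask@voxels else atlasMask
  if (all(img@voxels == 0)) stop("empty image")
  red <- dropCaudalThird(img)
  thr <- adaptiveVolumeThreshold(red, sum(atl))
  v <- red@voxels
  v[v <= thr$threshold] <- 0
  VolumeImage(v, img@spacing)
}

#' Auxiliary alignment image for target-selective tracers
#'
#' Combines the intensity-inverted VOI with the rostral half of the
#' animal's head at half intensity: (a) the dilated VOI is extracted from
#' the original image, contrast-stretched and inverted; (b) the whole image
#' is binarised and cavity-filled, cropped in x/y to the VOI bounding
#' cuboid and in z to the rostral half, and voxels already in the inverted
#' VOI are removed; (c) the original image is masked by this head mask and
#' halved; (d) the output is the sum of inverted VOI and halved head.
#'
#' @param img summed \code{VolumeImage}.
#' @param voi the segmented VOI \code{BinaryMask}.
#' @return A \code{VolumeImage}.
#' @export
buildAuxTarget <- function(img, voi) {
  assertVolume(img)
  v <- img@voxels
  voiM <- if (is(voi, "BinaryMask")) voi@voxels else voi
  storage.mode(voiM) <- "logical"
  if (!any(voiM)) stop("empty VOI")
  dil <- morph3(voiM, "dilate")
  inVoi <- array(0, dim(v))
  vals <- v[dil]
  r <- range(vals)
  inVoi[dil] <- if (r[2] > r[1]) 1 - (vals - r[1]) / (r[2] - r[1]) else 1
  # head mask
  bin <- v > 0
  dim(bin) <- dim(v)
  head <- cpp_fill_holes(bin)
  idx <- which(voiM, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  d <- dim(v)
  headCrop <- array(FALSE, d)
  zHalf <- seq_len(floor(d[3] / 2)) # rostral half (caudal at high z)
  headCrop[lo[1]:hi[1], lo[2]:hi[2], zHalf] <-
    head[lo[1]:hi[1], lo[2]:hi[2], zHalf]
  headCrop[dil] <- FALSE
  if (!any(headCrop)) {
    warning("head mask empty; returning inverted VOI only")
    return(VolumeImage(inVoi, img@spacing))
  }
  halved <- array(0, d)
  halved[headCrop] <- v[headCrop] / 2
  VolumeImage(inVoi + halved, img@spacing)
}

# ---- subject/state and template alignment ---------------------------------

#' Rigidly align disease states to the control state within each subject
#'
#' For every longitudinal series, each disease-state auxiliary image is
#' rigidly registered to the control-state auxiliary image and the
#' transform is applied to the subject's full dynamic data. Subjects
#' without a control state are left for direct template alignment with a
#' warning.
#'
#' @param series named list (one element per subject) of named lists of
#'   \code{DynamicImage}s keyed by state; the first state is taken as
#'   control (use \code{\link{detectRepeatMeasurements}} ordering).
#' @param auxFun function(summed VolumeImage, state) -> VolumeImage used to
#'   build the registration image; default passes the summed image through.
#' @return \code{list(aligned = same structure of DynamicImages,
#'   chains = per subject/state TransformChain)}.
#' @export
alignSubjectStates <- function(series, auxFun = function(img, state) img) {
  aligned <- series
  chains <- lapply(series, function(s) vector("list", length(s)))
  for (nm in names(series)) {
    states <- names(series[[nm]])
    chains[[nm]] <- stats::setNames(vector("list", length(states)), states)
    ctrlState <- states[1]
    ctrlAux <- auxFun(sumFrames(series[[nm]][[ctrlState]]), ctrlState)
    idChain <- new("TransformChain", transforms = list())
    chains[[nm]][[ctrlState]] <- idChain
    for (st in states[-1]) {
      movAux <- auxFun(sumFrames(series[[nm]][[st]]), st)
      tr <- rigidRegister(movAux, ctrlAux,
                          movingFrame = paste(nm, st, sep = ":"),
                          fixedFrame = paste(nm, ctrlState, sep = ":"))
      ch <- new("TransformChain", transforms = list(tr))
      aligned[[nm]][[st]] <- applyTransform(series[[nm]][[st]], ch)
      chains[[nm]][[st]] <- ch
    }
  }
  list(aligned = aligned, chains = chains)
}

#' Align all subjects to the PET template
#'
#' The control image of every subject is deformably registered to the
#' template image; the subject's other states reuse the control's transform
#' chain without re-registration (the alignment-transfer contract).
#'
#' @param subjects output of \code{\link{alignSubjectStates}} (list with
#'   \code{aligned} and \code{chains}).
#' @param template a \code{\linkS4class{Template}}.
#' @param iterations,tol deformable settings.
#' @return \code{list(aligned, chains)} in template space; chains map each
#'   state's original frame to template space.
#' @export
alignToTemplate <- function(subjects, template, iterations = 1000L,
                            tol = 1e-8) {
  out <- subjects$aligned
  chains <- subjects$chains
  for (nm in names(out)) {
    states <- names(out[[nm]])
    ctrlState <- states[1]
    ctrlSum <- sumFrames(out[[nm]][[ctrlState]])
    reg <- deformableRegister(ctrlSum, template@image,
                              iterations = iterations, tol = tol,
                              movingFrame = paste(nm, ctrlState, sep = ":"),
                              fixedFrame = "template")
    for (st in states) {
      newChain <- new("TransformChain",
                      transforms = c(chains[[nm]][[st]]@transforms,
                                     list(reg$transform)))
      out[[nm]][[st]] <- applyTransform(subjects$aligned[[nm]][[st]],
                                        list(reg$transform),
                                        outDim = dim(template@image@voxels),
                                        outSpacing = template@image@spacing)
      chains[[nm]][[st]] <- newChain
    }
  }
  list(aligned = out, chains = chains)
}

#' Second-template workflow for strongly altered uptake
#'
#' Builds a second template from a designated experimental group (VOI per
#' the metabolic procedure, reference per \code{\link{selectReference}}),
#' aligns that group's members to it rigidly with auxiliary structures
#' (never deformably, which the altered uptake would mislead), rigidly
#' registers the second template onto the primary template, and propagates
#' the chain so every member ends in primary-template space.
#'
#' @param groupImages named list of summed \code{VolumeImage}s of the
#'   designated experimental group.
#' @param groupMasks list of their VOI \code{BinaryMask}s.
#' @param primaryTemplate the primary \code{\linkS4class{Template}}.
#' @param atlasMask resized atlas support for the auxiliary builder.
#' @return \code{list(template2, aligned, chains, audit)}; \code{audit}
#'   records the registration kind used for every member.
#' @export
secondTemplateWorkflow <- function(groupImages, groupMasks, primaryTemplate,
                                   atlasMask) {
  n <- length(groupImages)
  if (n < 2L) stop("designated group too small for a second template (< 2)")
  ids <- names(groupImages)
  if (is.null(ids)) ids <- paste0("exp_", seq_len(n))
  refIdx <- selectReference(groupMasks)
  cen <- centerVoi(groupImages[[refIdx]], groupMasks[[refIdx]])
  audit <- character()
  aligned <- vector("list", n); names(aligned) <- ids
  chains <- vector("list", n); names(chains) <- ids
  refAux <- buildAuxMetabolic(cen$image, atlasMask)
  shiftTr <- new("Transform", kind = "rigid",
                 parameters = list(A = diag(3), b = as.numeric(-cen$shift)),
                 fixedFrame = "template2", movingFrame = ids[refIdx])
  for (i in seq_len(n)) {
    if (i == refIdx) {
      aligned[[i]] <- cen$image
      chains[[i]] <- new("TransformChain", transforms = list(shiftTr))
      audit <- c(audit, paste0(ids[i], ": rigid (reference shift)"))
      next
    }
    aux <- buildAuxMetabolic(groupImages[[i]], atlasMask)
    tr <- rigidRegister(aux, refAux, movingFrame = ids[i],
                        fixedFrame = "template2")
    aligned[[i]] <- applyTransform(groupImages[[i]], list(tr))
    chains[[i]] <- new("TransformChain", transforms = list(tr))
    audit <- c(audit, paste0(ids[i], ": rigid"))
  }
  tmpl2 <- VolumeImage(Reduce(`+`, lapply(aligned, voxels)) / n,
                       cen$image@spacing)
  # second template -> primary template, rigid
  trT <- rigidRegister(tmpl2, primaryTemplate@image,
                       movingFrame = "template2", fixedFrame = "template")
  audit <- c(audit, "template2 -> template: rigid")
  for (i in seq_len(n)) {
    chains[[i]] <- new("TransformChain",
                       transforms = c(chains[[i]]@transforms, list(trT)))
    aligned[[i]] <- applyTransform(aligned[[i]], list(trT),
                                   outDim = dim(primaryTemplate@image@voxels))
  }
  list(template2 = tmpl2, aligned = aligned, chains = chains, audit = audit)
}

#' Two-step affine co-registration of the template to MRI/atlas space
#'
#' Step 1 roughly aligns the gradient-magnitude images of the template and
#' the resized MRI T2* (affine, iteration cap 500, tolerance 1e-15); step 2
#' registers the template VOI volume onto the resized MRI brain volume with
#' a mutual-information metric (cap 2000, tolerance 1e-15). The returned
#' chain maps template space to atlas space; composed with subject chains,
#' every image can be carried into atlas space.
#'
#' @param template a \code{\linkS4class{Template}} with a segmented VOI.
#' @param mriResized resized MRI T2* \code{VolumeImage} on the PET grid.
#' @param fractionalAtlas the \code{\linkS4class{FractionalAtlas}} (for the
#'   brain support volume).
#' @return A \code{TransformChain} (template -> atlas space).
#' @export
coregisterToMri <- function(template, mriResized, fractionalAtlas) {
  g1 <- VolumeImage(gradientMagnitude(normalize01(template@image@voxels)),
                    template@image@spacing)
  g2 <- VolumeImage(gradientMagnitude(normalize01(mriResized@voxels)),
                    mriResized@spacing)
  step1 <- tryCatch(
    affineRegister(g1, g2, metric = "correlation", iterations = 500L,
                   tol = 1e-15, movingFrame = "template",
                   fixedFrame = "atlas_pre"),
    error = function(e) stop("co-registration step 1 (gradient) failed: ",
                             conditionMessage(e)))
  voiVol <- VolumeImage(array(as.double(template@voiMask@voxels),
                              dim(template@voiMask@voxels)),
                        template@image@spacing)
  voiPre <- applyTransform(voiVol, list(step1),
                           outDim = dim(mriResized@voxels))
  brainVol <- VolumeImage(
    array(as.double(fractionalAtlas@brainMask@voxels),
          dim(fractionalAtlas@brainMask@voxels)),
    fractionalAtlas@spacing)
  step2 <- tryCatch(
    affineRegister(voiPre, brainVol, metric = "mutual_information",
                   iterations = 2000L, tol = 1e-15,
                   movingFrame = "atlas_pre", fixedFrame = "atlas"),
    error = function(e) stop("co-registration step 2 (VOI) failed: ",
                             conditionMessage(e)))
  new("TransformChain", transforms = list(step1, step2))
}

# ---- similarity -----------------------------------------------------------

jointHistogramStats <- function(a, b, bins = 64L, mask = NULL) {
  av <- as.vector(a); bv <- as.vector(b)
  if (!is.null(mask)) { av <- av[mask]; bv <- bv[mask] }
  ra <- range(av); rb <- range(bv)
  degenerate <- ra[2] <= ra[1] || rb[2] <= rb[1]
  ia <- if (ra[2] > ra[1])
    pmin(1L + floor((av - ra[1]) / (ra[2] - ra[1]) * bins), bins) else
      rep(1L, length(av))
  ib <- if (rb[2] > rb[1])
    pmin(1L + floor((bv - rb[1]) / (rb[2] - rb[1]) * bins), bins) else
      rep(1L, length(bv))
  jh <- matrix(tabulate((ia - 1L) * bins + ib, nbins = bins * bins),
               bins, bins)
  p <- jh / sum(jh)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  Hj <- ent(p)
  Ha <- ent(rowSums(t(p)))  # over a-bins
  Hb <- ent(colSums(t(p)))
  list(joint_entropy = Hj, entropy_a = Ha, entropy_b = Hb,
       mutual_information = max(0, Ha + Hb - Hj), degenerate = degenerate)
}

#' Similarity report between two volumes
#'
#' Pearson and Spearman correlation over (masked) voxel pairs plus joint
#' entropy and mutual information in bits from a 64 x 64 joint histogram.
#' Computed before and after registrations to track alignment quality.
#'
#' @param a,b \code{VolumeImage}s of the same shape.
#' @param mask optional \code{BinaryMask} restricting the comparison
#'   (e.g. the VOI).
#' @param scope,phase labels recorded in the report (\code{"full_image"} /
#'   \code{"voi"}; \code{"before"} / \code{"after"}).
#' @return list with pearson, spearman, joint_entropy,
#'   mutual_information, scope, phase, degenerate.
#' @export
similarityReport <- function(a, b, mask = NULL, scope = "full_image",
                             phase = "before") {
  assertVolume(a, "a"); assertVolume(b, "b")
  if (!identical(dim(a@voxels), dim(b@voxels))) stop("shapes differ")
  m <- if (is.null(mask)) NULL else as.vector(mask@voxels)
  av <- as.vector(a@voxels); bv <- as.vector(b@voxels)
  if (!is.null(m)) { av <- av[m]; bv <- bv[m] }
  degenerate <- stats::sd(av) == 0 || stats::sd(bv) == 0
  pe <- if (degenerate) NA_real_ else stats::cor(av, bv)
  sp <- if (degenerate) NA_real_ else stats::cor(av, bv, method = "spearman")
  jh <- jointHistogramStats(av, bv, 64L)
  list(pearson = pe, spearman = sp, joint_entropy = jh$joint_entropy,
       mutual_information = jh$mutual_information, scope = scope,
       phase = phase, degenerate = degenerate || jh$degenerate)
}
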