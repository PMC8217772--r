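# Config-driven end-to-end orchestration (module: cli_pipeline):
# preprocess -> atlas resample -> segment -> template -> align ->
# (optional 2nd template) -> co-register -> quantify -> statistics, with
# per-stage QC artifacts and a reproducibility manifest.

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, checks all required fields and
#' cross-references, and reports every violation in one aggregated error.
#'
#' @param path path to the YAML config (or a pre-parsed list).
#' @return The validated config list (with defaults filled in).
#' @export
validateConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  errs <- character()
  need <- function(field, check = function(x) !is.null(x), msg = "missing") {
    ok <- tryCatch(check(cfg[[field]]), error = function(e) FALSE)
    if (!isTRUE(ok)) errs <<- c(errs, paste0("field '", field, "': ", msg))
  }
  need("output_dir")
  need("tracer_mode",
       function(x) x %in% c("metabolic", "target_selective"),
       "must be 'metabolic' or 'target_selective'")
  need("seed", function(x) is.numeric(x) && x == round(x), "integer required")
  defaults <- list(mode = "phantom", n_animals = 3L,
                   states = c("healthy", "stroke"),
                   exclude_slices = 5L, min_neighbors = 5L,
                   frame_minutes = 10, n_frames = 6L,
                   intervals = list(c(0, 60)),
                   reference_region = "whole_voi", paired = TRUE,
                   second_template = FALSE, deformable_iterations = 120L,
                   group_effects = list(), noise_sigma = 3.5,
                   pet_dim = c(64L, 64L, 80L),
                   pet_resolution_um = c(776, 776, 796),
                   scale_denominator = 3L, plots = TRUE)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (!cfg$mode %in% c("phantom", "files"))
    errs <- c(errs, "field 'mode': must be 'phantom' or 'files'")
  if (cfg$mode == "files") {
    for (f in c("input_dir", "metadata_csv"))
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        errs <- c(errs, paste0("field '", f, "': path missing or nonexistent"))
  }
  cfg$intervals <- lapply(cfg$intervals, as.numeric)
  for (iv in cfg$intervals) {
    if (length(iv) != 2L || iv[2] <= iv[1]) {
      errs <- c(errs, "field 'intervals': each entry must be [start, end] minutes")
      next
    }
    if (any(iv %% cfg$frame_minutes != 0))
      errs <- c(errs, sprintf(
        "field 'intervals': [%g, %g] does not tile %g-minute frames",
        iv[1], iv[2], cfg$frame_minutes))
  }
  if (length(cfg$states) < 1L) errs <- c(errs, "field 'states': need >= 1")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg
}

logStage <- function(log, ...) {
  msg <- paste0(...)
  message("[petquant] ", msg)
  c(log, msg)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a phantom cohort (\code{mode: phantom}) or on
#' NIfTI inputs (\code{mode: files}), emitting per-stage QC artifacts
#' (masks, similarity CSV), the tidy quantification CSV, the statistics
#' CSV, plots and a run manifest. A failing stage aborts with its name;
#' artifacts produced up to that point remain in the output directory.
#'
#' @param config path to a YAML config or a config list (validated with
#'   \code{\link{validateConfig}}).
#' @return The output directory, invisibly.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  set.seed(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- inputs ---------------------------------------------------------------
  log <- logStage(log, "stage: inputs (", cfg$mode, ")")
  if (cfg$mode == "phantom") {
    spec <- phantomSpec(petDim = cfg$pet_dim,
                        petSpacing = cfg$pet_resolution_um,
                        scaleDenominator = cfg$scale_denominator,
                        tracerMode = cfg$tracer_mode,
                        noiseSigma = cfg$noise_sigma,
                        nFrames = cfg$n_frames,
                        frameMinutes = cfg$frame_minutes,
                        seed = cfg$seed)
    ph <- stage("inputs", makeAtlasPhantom(spec))
    cohort <- stage("inputs",
                    makePetCohort(spec, cfg$n_animals, cfg$states,
                                  groupEffects = cfg$group_effects))
    mri <- ph$mri; atlas <- ph$atlas
    images <- cohort$images; records <- cohort$records
  } else {
    meta <- utils::read.csv(cfg$metadata_csv, stringsAsFactors = FALSE)
    images <- list()
    for (i in seq_len(nrow(meta))) {
      img <- readVolume(file.path(cfg$input_dir, meta$file[i]))
      images[[meta$animal_id[i]]][[meta$state[i]]] <- img
    }
    records <- meta
    mri <- { d <- readVolume(cfg$mri_path); VolumeImage(d@voxels[, , , 1],
                                                        d@spacing) }
    atlas <- readLabelAtlas(cfg$atlas_path, cfg$atlas_labels_path)
  }

  # -- preprocessing --------------------------------------------------------
  log <- logStage(log, "stage: preprocess")
  reports <- list()
  for (a in names(images)) for (st in names(images[[a]])) {
    pp <- stage("preprocess",
                preprocessImage(images[[a]][[st]], cfg$exclude_slices,
                                cfg$min_neighbors))
    images[[a]][[st]] <- pp$image
    reports[[paste(a, st, sep = ":")]] <- pp$report
  }
  summed <- lapply(images, function(s) lapply(s, sumFrames))
  # within-group (state) intensity factors, alignment-only
  states <- unique(records$state)
  factors <- list()
  for (st in states) {
    imgs <- lapply(names(images), function(a) summed[[a]][[st]])
    fac <- stage("preprocess", groupIntensityFactors(imgs))
    for (k in seq_along(fac)) {
      a <- names(images)[k]
      summed[[a]][[st]]@voxels <- summed[[a]][[st]]@voxels * fac[k]
      reports[[paste(a, st, sep = ":")]]$multiplication_factor <- fac[k]
    }
    factors[[st]] <- fac
  }
  jsonlite::write_json(reports, file.path(out, "preprocess_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- atlas resampling -----------------------------------------------------
  log <- logStage(log, "stage: atlas")
  sf <- stage("atlas", computeScaleFactor(cfg$pet_resolution_um[1],
                                          atlas@spacing[1]))
  fracAtlas <- stage("atlas", resizeSubregions(atlas, sf))
  mriResized <- stage("atlas", resizeVolume(mri, sf))
  writeVolume(fracAtlas@brainMask, file.path(out, "qc_atlas_brain_mask.nii.gz"))
  # atlas support on the preprocessed PET grid for segmentation
  petDimPre <- dim(summed[[1]][[1]]@voxels)
  atlasMaskPet <- padCropTo(fracAtlas@brainMask@voxels, petDimPre)

  # -- VOI segmentation of controls ----------------------------------------
  log <- logStage(log, "stage: segment")
  ctrlState <- cfg$states[1]
  segFun <- if (cfg$tracer_mode == "metabolic") segmentVoiMetabolic
            else segmentVoiTargetSelective
  segs <- list()
  for (a in names(summed)) {
    segs[[a]] <- stage("segment", segFun(summed[[a]][[ctrlState]],
                                         atlasMaskPet))
    writeVolume(segs[[a]]@voiMask,
                file.path(out, paste0("qc_voi_", a, ".nii.gz")))
  }
  segReport <- lapply(segs, function(s)
    list(score = s@matchScore, rotation_deg = s@bestRotation,
         threshold = s@thresholdUsed))
  jsonlite::write_json(segReport, file.path(out, "segmentation_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- template -------------------------------------------------------------
  log <- logStage(log, "stage: template")
  ctrlImgs <- lapply(names(summed), function(a) summed[[a]][[ctrlState]])
  ctrlMasks <- lapply(names(summed), function(a) segs[[a]]@voiMask)
  refIdx <- stage("template", selectReference(ctrlMasks))
  template <- stage("template",
                    buildTemplate(ctrlImgs, ctrlMasks, refIdx,
                                  ids = names(summed),
                                  iterations = cfg$deformable_iterations))
  if (cfg$tracer_mode == "target_selective")
    template@voiMask <- stage("template",
                              segmentTemplateVoiInverted(template@image))
  writeVolume(template@image, file.path(out, "template.nii.gz"))
  writeVolume(template@voiMask, file.path(out, "template_voi.nii.gz"))
  log <- logStage(log, "template reference: ", template@referenceId)

  # -- alignment ------------------------------------------------------------
  log <- logStage(log, "stage: align")
  auxFun <- if (cfg$tracer_mode == "metabolic") {
    function(img, state) buildAuxMetabolic(img, atlasMaskPet)
  } else {
    function(img, state) img
  }
  simRows <- list()
  withSim <- function(nm, phase, a, b, mask = NULL) {
    r <- similarityReport(a, b, mask = mask, phase = phase)
    simRows[[length(simRows) + 1L]] <<-
      data.frame(subject = nm, scope = r$scope, phase = phase,
                 pearson = r$pearson, spearman = r$spearman,
                 joint_entropy = r$joint_entropy,
                 mutual_information = r$mutual_information)
  }
  subj <- stage("align", alignSubjectStates(images, auxFun))
  atTemplate <- stage("align", alignToTemplate(subj, template,
                                               iterations =
                                                 cfg$deformable_iterations))
  for (a in names(atTemplate$aligned)) {
    withSim(a, "before", sumFrames(images[[a]][[ctrlState]]), template@image)
    withSim(a, "after", sumFrames(atTemplate$aligned[[a]][[ctrlState]]),
            template@image)
  }

  # -- optional second template --------------------------------------------
  if (isTRUE(cfg$second_template)) {
    log <- logStage(log, "stage: second template (rigid-only group alignment)")
    expState <- cfg$states[length(cfg$states)]
    expImgs <- lapply(names(summed), function(a) summed[[a]][[expState]])
    names(expImgs) <- names(summed)
    expMasks <- lapply(names(summed), function(a) {
      segFun(summed[[a]][[expState]], atlasMaskPet)@voiMask
    })
    st2 <- stage("second_template",
                 secondTemplateWorkflow(expImgs, expMasks, template,
                                        atlasMaskPet))
    writeLines(st2$audit, file.path(out, "second_template_audit.log"))
  }

  # -- co-registration to MRI/atlas ----------------------------------------
  log <- logStage(log, "stage: coregister")
  coChain <- stage("coregister",
                   coregisterToMri(template, mriResized, fracAtlas))
  tmplInAtlas <- applyTransform(template@image, coChain,
                                outDim = dim(mriResized@voxels),
                                outSpacing = mriResized@spacing)
  withSim("template_vs_mri", "after", tmplInAtlas, mriResized,
          mask = fracAtlas@brainMask)
  simTab <- do.call(rbind, simRows)
  utils::write.csv(simTab, file.path(out, "similarity.csv"),
                   row.names = FALSE)

  # -- transform dynamic data to atlas space -------------------------------
  log <- logStage(log, "stage: resample to atlas space")
  atlasDim <- dim(mriResized@voxels)
  aligned <- list()
  for (a in names(images)) {
    aligned[[a]] <- list()
    for (st in names(images[[a]])) {
      fullChain <- new("TransformChain",
                       transforms = c(atTemplate$chains[[a]][[st]]@transforms,
                                      coChain@transforms))
      aligned[[a]][[st]] <- stage("resample",
        applyTransform(images[[a]][[st]], fullChain, outDim = atlasDim,
                       outSpacing = mriResized@spacing))
    }
  }

  # -- quantification -------------------------------------------------------
  log <- logStage(log, "stage: quantify")
  refRegion <- cfg$reference_region
  if (!identical(refRegion, "whole_voi") && !is.numeric(refRegion)) {
    hit <- fracAtlas@labelTable$id[fracAtlas@labelTable$name == refRegion]
    if (length(hit) == 1L) refRegion <- hit
  }
  quant <- stage("quantify",
                 quantifyCohort(aligned, fracAtlas, records, cfg$intervals,
                                referenceRegion = refRegion))
  # region names in the output table
  qt <- quant@table
  qt$region <- fracAtlas@labelTable$name[
    match(as.integer(qt$region), fracAtlas@labelTable$id)]
  quantNamed <- new("QuantResult", table = qt,
                    referenceRegion = as.character(cfg$reference_region))
  writeQuantCsv(quantNamed, file.path(out, "quantification.csv"))

  # -- statistics -----------------------------------------------------------
  if (length(cfg$states) >= 2L) {
    log <- logStage(log, "stage: statistics")
    statRes <- stage("statistics",
                     runRegionStats(quantNamed, paired = cfg$paired,
                                    plotDir = if (isTRUE(cfg$plots))
                                      file.path(out, "plots") else NULL))
    utils::write.csv(statRes, file.path(out, "statistics.csv"),
                     row.names = FALSE)
  }

  # -- manifest -------------------------------------------------------------
  cfgNoOut <- cfg; cfgNoOut$output_dir <- NULL
  manifest <- list(
    config_hash = sum(utf8ToInt(paste(deparse(cfgNoOut), collapse = ""))),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("petquant")),
    stages = log)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

# pad or crop a 3-D array symmetrically to the requested dims
padCropTo <- function(arr, dm) {
  d <- dim(arr)
  out <- array(if (is.logical(arr)) FALSE else 0, dm)
  srcStart <- pmax(1, floor((d - dm) / 2) + 1)
  dstStart <- pmax(1, floor((dm - d) / 2) + 1)
  len <- pmin(d - srcStart + 1, dm - dstStart + 1)
  out[dstStart[1]:(dstStart[1] + len[1] - 1),
      dstStart[2]:(dstStart[2] + len[2] - 1),
      dstStart[3]:(dstStart[3] + len[3] - 1)] <-
    arr[srcStart[1]:(srcStart[1] + len[1] - 1),
        srcStart[2]:(srcStart[2] + len[2] - 1),
        srcStart[3]:(srcStart[3] + len[3] - 1)]
  out
}
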