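# Digital rodent-head phantoms with known ground truth
# (module: phantom_fixtures). An ellipsoidal "brain" partitioned into
# axial-slab sub-regions stands in for the high-resolution MRI atlas;
# dynamic PET cohorts are synthesised from it with known per-animal rigid
# perturbations, group effects and Poisson-surrogate noise, so every
# pipeline stage can be validated without any download.

#' Phantom specification
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: a 64 x 64 x 80 PET grid at 776 x 776 x 796 um with a 3x
#' higher-resolution MRI/atlas grid, an ellipsoidal brain with five
#' labelled axial-slab sub-regions (olfactory, cortex, thalamus,
#' hippocampus, cerebellum; the cortex is splittable into hemispheres), six
#' 10-minute frames, and mild rigid perturbations per animal.
#'
#' @param petDim PET grid dims (default c(64, 64, 80)).
#' @param petSpacing PET voxel size, um (default c(776, 776, 796)).
#' @param scaleDenominator integer k: MRI spacing = PET in-plane / k
#'   (default 3).
#' @param brainSemiAxes brain ellipsoid semi-axes in PET voxels
#'   (default c(13, 10, 19)).
#' @param brainCenterFrac brain centre as a fraction of the PET grid
#'   (default c(0.5, 0.5, 0.38); the caudal third stays empty).
#' @param tracerMode "metabolic" or "target_selective".
#' @param lesion list(center_offset_vox, radius_vox, contrast) for the
#'   focal lesion (target-selective mode).
#' @param hotspots list(offset_vox, radius_vox, contrast) for the paired
#'   anterior Harderian-like hotspots (metabolic mode).
#' @param noiseSigma Gaussian noise scale; voxel variance is
#'   \code{noiseSigma^2 * intensity} (Poisson surrogate). The default 3.5
#'   gives about 5 percent voxelwise CV at a 5 kBq/mL tissue level.
#' @param nFrames number of 10-minute frames (default 6).
#' @param frameMinutes frame duration in minutes (default 10).
#' @param maxRotationDeg,maxTranslationVox bounds of the per-animal rigid
#'   ground-truth perturbation (defaults 6 and 2.5).
#' @param regionMeans named per-region baseline uptake (kBq/mL-scale);
#'   defaults near 5 with mild regional variation.
#' @param seed integer RNG seed.
#' @return A list (class \code{phantomSpec}) of the above.
#' @export
phantomSpec <- function(petDim = c(64L, 64L, 80L),
                        petSpacing = c(776, 776, 796),
                        scaleDenominator = 3L,
                        brainSemiAxes = c(13, 10, 16),
                        brainCenterFrac = c(0.5, 0.5, 0.36),
                        tracerMode = c("metabolic", "target_selective"),
                        lesion = list(center_offset_vox = c(4, -3, -5),
                                      radius_vox = 3.5, contrast = 10),
                        hotspots = list(offset_vox = c(6, -6, -13),
                                        radius_vox = 2.2, contrast = 1.5),
                        noiseSigma = 3.5,
                        nFrames = 6L, frameMinutes = 10,
                        maxRotationDeg = 6, maxTranslationVox = 2.5,
                        regionMeans = c(olfactory = 4.2, cortex = 5.5,
                                        thalamus = 6.0, hippocampus = 5.0,
                                        cerebellum = 5.2),
                        seed = 1L) {
  tracerMode <- match.arg(tracerMode)
  spec <- list(petDim = as.integer(petDim), petSpacing = petSpacing,
               scaleDenominator = as.integer(scaleDenominator),
               brainSemiAxes = brainSemiAxes,
               brainCenterFrac = brainCenterFrac, tracerMode = tracerMode,
               lesion = lesion, hotspots = hotspots,
               noiseSigma = noiseSigma, nFrames = as.integer(nFrames),
               frameMinutes = frameMinutes,
               maxRotationDeg = maxRotationDeg,
               maxTranslationVox = maxTranslationVox,
               regionMeans = regionMeans, seed = as.integer(seed))
  if (any(brainSemiAxes * 2 >= petDim))
    stop("brain semi-axes must fit inside the PET grid")
  class(spec) <- "phantomSpec"
  spec
}

# z-slab boundaries of the five regions as fractions of [-c, c]
regionSlabFracs <- function() {
  c(-1, -0.55, -0.05, 0.35, 0.62, 1)
}

# ellipsoid interior indicator on an arbitrary grid
ellipsoidField <- function(dm, center, semi) {
  x <- (seq_len(dm[1]) - center[1]) / semi[1]
  y <- (seq_len(dm[2]) - center[2]) / semi[2]
  z <- (seq_len(dm[3]) - center[3]) / semi[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

#' Generate the high-resolution MRI T2*-like volume and label atlas
#'
#' The brain is an ellipsoid partitioned into five axial slabs (rostral to
#' caudal: olfactory, cortex, thalamus, hippocampus, cerebellum) whose
#' volumes have closed-form ellipsoid-slab expressions. T2*-like
#' intensities are a per-region base plus a smooth low-frequency field.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return \code{list(mri = VolumeImage, atlas = LabelAtlas,
#'   analyticVolumes = named numeric (voxel units of the MRI grid))}.
#' @export
makeAtlasPhantom <- function(spec) {
  k <- spec$scaleDenominator
  dm <- spec$petDim * k
  mriSpacing <- spec$petSpacing / k
  center <- spec$brainCenterFrac * dm + 0.5
  semi <- spec$brainSemiAxes * k
  ef <- ellipsoidField(dm, center, semi)
  inside <- ef <= 1
  lab <- array(0L, dm)
  fr <- regionSlabFracs()
  zRel <- (seq_len(dm[3]) - center[3]) / semi[3]
  for (r in seq_len(length(fr) - 1L)) {
    sel <- zRel > fr[r] & zRel <= fr[r + 1L]
    slab <- array(rep(sel, each = dm[1] * dm[2]), dm)
    lab[inside & slab] <- r
  }
  tab <- data.frame(id = 1:5,
                    name = c("olfactory", "cortex", "thalamus",
                             "hippocampus", "cerebellum"))
  # analytic slab volumes: V = pi a b integral (1 - t^2) dt over [t0, t1], c
  a <- semi[1]; b <- semi[2]; cc <- semi[3]
  slabVol <- function(t0, t1) {
    t0 <- max(t0, -1); t1 <- min(t1, 1)
    pi * a * b * cc * ((t1 - t1^3 / 3) - (t0 - t0^3 / 3))
  }
  av <- vapply(seq_len(5), function(r) slabVol(fr[r], fr[r + 1]), numeric(1))
  names(av) <- tab$name
  # T2*-like intensities
  base <- c(0.45, 0.75, 0.6, 0.68, 0.55)
  t2 <- array(0.1, dm)
  for (r in 1:5) t2[lab == r] <- base[r]
  gx <- sin(2 * pi * (seq_len(dm[1])) / dm[1])
  gz <- cos(2 * pi * (seq_len(dm[3])) / dm[3])
  smooth <- 0.05 * outer(outer(gx, rep(1, dm[2])), gz)
  t2 <- t2 + smooth
  t2[!inside] <- 0.08
  list(mri = VolumeImage(t2, mriSpacing),
       atlas = LabelAtlas(lab, mriSpacing, tab),
       analyticVolumes = av)
}

# nearest-neighbour label downsample to the PET grid (ground-truth support)
petGridLabels <- function(spec) {
  k <- spec$scaleDenominator
  dm <- spec$petDim
  center <- spec$brainCenterFrac * dm + 0.5
  semi <- spec$brainSemiAxes
  ef <- ellipsoidField(dm, center, semi)
  inside <- ef <= 1
  lab <- array(0L, dm)
  fr <- regionSlabFracs()
  zRel <- (seq_len(dm[3]) - center[3]) / semi[3]
  for (r in seq_len(length(fr) - 1L)) {
    sel <- zRel > fr[r] & zRel <= fr[r + 1L]
    slab <- array(rep(sel, each = dm[1] * dm[2]), dm)
    lab[inside & slab] <- r
  }
  lab
}

# noise-free tracer pattern on the PET grid (Bq/mL) plus ground truth;
# regionMeans are kBq/mL and converted here
tracerPattern <- function(spec, stateEffects = NULL) {
  dm <- spec$petDim
  lab <- petGridLabels(spec)
  means <- spec$regionMeans
  if (!is.null(stateEffects))
    means <- means * stateEffects[names(means)]
  means <- means * 1000
  pat <- array(0, dm)
  for (r in seq_along(means)) pat[lab == r] <- means[r]
  center <- spec$brainCenterFrac * dm + 0.5
  if (spec$tracerMode == "metabolic") {
    # paired anterior Harderian-like hotspots outside the brain
    off <- spec$hotspots$offset_vox
    amp <- spec$hotspots$contrast * max(means)
    for (sgn in c(-1, 1)) {
      hc <- center + c(sgn * abs(off[1]) + sgn * spec$brainSemiAxes[1],
                       off[2], off[3])
      hs <- ellipsoidField(dm, hc, rep(spec$hotspots$radius_vox, 3)) <= 1
      pat[hs] <- amp
    }
  } else {
    # dim brain, bright focal lesion, brighter surrounding head tissue
    headSemi <- spec$brainSemiAxes * c(1.3, 1.3, 1.15)
    headAll <- ellipsoidField(dm, center, headSemi) <= 1
    pat[headAll & lab == 0] <- spec$lesion$contrast * 0.3 * 1000
    pat[lab > 0] <- 1000
    lc <- center + spec$lesion$center_offset_vox
    ls <- ellipsoidField(dm, lc, rep(spec$lesion$radius_vox, 3)) <= 1
    pat[ls & lab > 0] <- spec$lesion$contrast * 1000
  }
  list(pattern = pat, labels = lab, brainMask = lab > 0)
}

#' Generate a dynamic PET cohort with known ground truth
#'
#' Per animal and state: the tracer pattern (metabolic: regional uptake
#' plus Harderian-like hotspots; target-selective: dim brain, focal lesion,
#' head shell) is modulated by any group effect, rigidly perturbed by a
#' known per-animal transform, expanded into frames with a monotone
#' time-activity scaling, and degraded with intensity-proportional Gaussian
#' noise. Each animal draws from its own seeded RNG stream, so cohorts are
#' bitwise reproducible.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param nAnimals number of animals.
#' @param states character vector of states (first = control); all animals
#'   carry all states.
#' @param groupEffects named list state -> named numeric multipliers per
#'   region (1 = no effect); absent entries default to 1.
#' @return list with \code{images} (animal -> state -> DynamicImage),
#'   \code{records} (data.frame: animal_id, group, state,
#'   injected_activity_Bq, body_weight_g, tracer_mode) and
#'   \code{groundTruth} (per animal: transform angles/translation; per
#'   state: region means; plus the PET-grid brain mask and labels).
#' @export
makePetCohort <- function(spec, nAnimals = 6L, states = c("healthy"),
                          groupEffects = list()) {
  images <- list(); gt <- list(); recs <- list()
  tacs <- seq(0.85, 1.15, length.out = spec$nFrames)
  fs <- frameTable((seq_len(spec$nFrames) - 1) * spec$frameMinutes * 60,
                   seq_len(spec$nFrames) * spec$frameMinutes * 60)
  baseMask <- tracerPattern(spec)$brainMask
  for (i in seq_len(nAnimals)) {
    animal <- sprintf("Rat_No_%d", i)
    set.seed(spec$seed * 10000L + i)
    ang <- stats::runif(3, -spec$maxRotationDeg, spec$maxRotationDeg)
    trn <- stats::runif(3, -spec$maxTranslationVox, spec$maxTranslationVox)
    injected <- stats::runif(1, 25e6, 40e6)
    weight <- stats::runif(1, 250, 350)
    images[[animal]] <- list()
    gtStates <- list()
    for (st in states) {
      eff <- rep(1, length(spec$regionMeans))
      names(eff) <- names(spec$regionMeans)
      if (!is.null(groupEffects[[st]])) {
        ge <- unlist(groupEffects[[st]])
        eff[names(ge)] <- ge
      }
      tp <- tracerPattern(spec, stateEffects = eff)
      moved <- rotateTranslateArray(tp$pattern, ang, trn)
      frames <- array(0, c(spec$petDim, spec$nFrames))
      for (f in seq_len(spec$nFrames)) {
        fr <- moved * tacs[f]
        if (spec$noiseSigma > 0)
          fr <- fr + stats::rnorm(length(fr), 0,
                                  spec$noiseSigma * sqrt(pmax(fr, 0)))
        frames[, , , f] <- pmax(fr, 0)
      }
      images[[animal]][[st]] <- DynamicImage(frames, spec$petSpacing, fs,
                                             meta = list(animal = animal,
                                                         state = st))
      gtStates[[st]] <- list(regionMeans = spec$regionMeans * eff)
      recs[[length(recs) + 1L]] <- data.frame(
        animal_id = animal, group = st, state = st,
        injected_activity_Bq = injected, body_weight_g = weight,
        tracer_mode = spec$tracerMode)
    }
    gt[[animal]] <- list(angles_deg = ang, translation_vox = trn,
                         states = gtStates)
  }
  list(images = images, records = do.call(rbind, recs),
       groundTruth = c(gt, list(.brainMask = baseMask,
                                .labels = petGridLabels(spec))))
}

#' Simulate a quantification table directly from the ground-truth model
#'
#' Generates the per-animal, per-region uptake-ratio values the imaging
#' pipeline would measure, without running the imaging stages: region means
#' times state effect, a per-animal lognormal random effect and
#' multiplicative measurement noise. Used for statistical calibration
#' experiments (e.g. type-I error under the null) where hundreds of cohorts
#' are needed.
#'
#' @param nAnimals animals per cohort.
#' @param states states (first = control).
#' @param regionMeans named baseline means.
#' @param groupEffects as in \code{\link{makePetCohort}}.
#' @param cvAnimal between-animal coefficient of variation (default 0.1).
#' @param cvNoise residual measurement CV (default 0.08).
#' @param referenceRegion UR denominator region (default "cerebellum").
#' @return A \code{\linkS4class{QuantResult}} with one interval.
#' @export
simulateQuantCohort <- function(nAnimals = 6L,
                                states = c("sham", "ptu", "pts"),
                                regionMeans = c(olfactory = 4.2,
                                                cortex = 5.5, thalamus = 6.0,
                                                hippocampus = 5.0,
                                                cerebellum = 5.2),
                                groupEffects = list(),
                                cvAnimal = 0.1, cvNoise = 0.08,
                                referenceRegion = "cerebellum") {
  rows <- list()
  for (i in seq_len(nAnimals)) {
    animal <- sprintf("Rat_No_%d", i)
    re <- stats::rlnorm(1, 0, cvAnimal)
    injected <- stats::runif(1, 25e6, 40e6)
    for (st in states) {
      eff <- rep(1, length(regionMeans)); names(eff) <- names(regionMeans)
      if (!is.null(groupEffects[[st]])) {
        ge <- unlist(groupEffects[[st]]); eff[names(ge)] <- ge
      }
      act <- regionMeans * eff * re *
        stats::rlnorm(length(regionMeans), 0, cvNoise)
      refAct <- act[[referenceRegion]]
      for (r in names(regionMeans)) {
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = animal, group = st, state = st, region = r,
          interval = "0-60 min",
          A_N = act[[r]] / 20, SUV = act[[r]] / 5,
          UR = act[[r]] / refAct)
      }
    }
  }
  new("QuantResult", table = do.call(rbind, rows),
      referenceRegion = referenceRegion)
}
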