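# Semi-quantitative uptake parameters per atlas sub-region
# (module: quantification). Quantification always reads the original
# dynamic frames: the group intensity-normalisation factor and the summed
# image are alignment-only.

#' Fractional-membership activity and volume of a region
#'
#' Activity is the fraction-weighted sum of concentration times voxel
#' volume; volume is the fraction-weighted voxel volume. Negative voxel
#' values (interpolation undershoot) are clamped to zero before
#' aggregation.
#'
#' @param imgFrame \code{VolumeImage} in atlas space, voxel values in Bq/mL.
#' @param fractions a \code{\linkS4class{FractionalAtlas}}.
#' @param region region id (or \code{"whole_voi"} for the union of all
#'   regions).
#' @return \code{list(activity_Bq, volume_mL, concentration_Bq_per_mL)}.
#' @export
regionActivity <- function(imgFrame, fractions, region) {
  assertVolume(imgFrame, "imgFrame")
  voxVolML <- prod(fractions@spacing) * 1e-12 # um^3 -> mL (1 mL = 1e12 um^3)
  conc <- pmax(imgFrame@voxels, 0)
  fr <- if (identical(region, "whole_voi"))
    Reduce(`+`, fractions@fractions)
  else regionFractions(fractions, region)
  if (!identical(dim(fr), dim(conc)))
    stop("image and atlas grids differ")
  act <- sum(fr * conc) * voxVolML
  vol <- sum(fr) * voxVolML
  list(activity_Bq = act, volume_mL = vol,
       concentration_Bq_per_mL = if (vol > 0) act / vol else NA_real_)
}

#' Normalized activity A_N
#'
#' Region activity divided by injected activity (dimensionless).
#'
#' @param regionActivityBq region activity in Bq.
#' @param injectedBq injected activity in Bq (> 0).
#' @return A_N.
#' @export
normalizedActivity <- function(regionActivityBq, injectedBq) {
  if (injectedBq <= 0) stop("injected activity must be positive")
  regionActivityBq / injectedBq
}

#' Standardized uptake value
#'
#' Region concentration divided by injected activity per body weight:
#' \code{SUV = C / (injected / weight)}, in g/mL.
#'
#' @param regionConcentration region concentration, Bq/mL.
#' @param injectedBq injected activity, Bq.
#' @param bodyWeightG body weight, g.
#' @return SUV in g/mL.
#' @examples
#' suv(5000, 25e6, 250)  # 0.05
#' @export
suv <- function(regionConcentration, injectedBq, bodyWeightG) {
  if (injectedBq <= 0 || bodyWeightG <= 0)
    stop("injected activity and body weight must be positive")
  if (!is.finite(regionConcentration))
    stop("region concentration undefined (zero region volume?)")
  regionConcentration / (injectedBq / bodyWeightG)
}

#' Uptake ratio
#'
#' Region activity divided by the reference activity: the whole VOI, or a
#' reference sub-region (e.g. the cerebellum when surgery makes whole-brain
#' normalisation inappropriate). Computed on activities (Bq) by default; a
#' concentration-based (SUVR-like) variant divides concentrations instead.
#'
#' @param regionActivityBq region activity (or concentration when
#'   \code{concentrationBased}).
#' @param referenceActivityBq reference activity (> 0) over the same
#'   interval.
#' @param concentrationBased logical flag for the SUVR-like variant; the
#'   caller passes concentrations in that case.
#' @return UR (dimensionless).
#' @export
uptakeRatio <- function(regionActivityBq, referenceActivityBq,
                        concentrationBased = FALSE) {
  if (referenceActivityBq <= 0) stop("reference activity must be positive")
  regionActivityBq / referenceActivityBq
}

# sum frames of a DynamicImage falling inside [startMin, endMin)
sumInterval <- function(img, startMin, endMin) {
  fs <- img@frameSchedule
  s <- startMin * 60; e <- endMin * 60
  sel <- fs$start_s >= s - 1e-9 & fs$end_s <= e + 1e-9
  startsOk <- any(abs(fs$start_s - s) < 1e-9)
  endsOk <- any(abs(fs$end_s - e) < 1e-9)
  if (!startsOk || !endsOk || !any(sel))
    stop("interval [", startMin, ", ", endMin, ") min does not tile whole ",
         "frames; valid boundaries (min): ",
         paste(unique(c(fs$start_s, fs$end_s)) / 60, collapse = ", "))
  arr <- img@voxels[, , , which(sel), drop = FALSE]
  VolumeImage(apply(arr, 1:3, sum), img@spacing)
}

#' Quantify a cohort per region, interval and animal
#'
#' For each animal/state and time interval the dynamic frames inside the
#' interval are summed (original data, not the alignment-only summed
#' image), then A_N, SUV and UR are computed for every atlas sub-region
#' using fractional membership.
#'
#' @param alignedImages named list (animal) of named lists (state) of
#'   \code{DynamicImage}s in atlas space.
#' @param fractions a \code{\linkS4class{FractionalAtlas}}.
#' @param records data.frame with columns animal_id, state, group,
#'   injected_activity_Bq, body_weight_g.
#' @param intervals list of \code{c(start_min, end_min)} pairs; each must
#'   tile whole frames.
#' @param referenceRegion region id for the UR denominator, or
#'   \code{"whole_voi"} (default).
#' @param concentrationBasedUR SUVR-like UR variant flag.
#' @return A \code{\linkS4class{QuantResult}}.
#' @export
quantifyCohort <- function(alignedImages, fractions, records, intervals,
                           referenceRegion = "whole_voi",
                           concentrationBasedUR = FALSE) {
  ids <- names(fractions@fractions)
  rows <- list()
  for (animal in names(alignedImages)) {
    for (state in names(alignedImages[[animal]])) {
      rec <- records[records$animal_id == animal & records$state == state, ]
      if (nrow(rec) != 1L)
        stop("no unique study record for ", animal, " / ", state)
      img <- alignedImages[[animal]][[state]]
      for (iv in intervals) {
        vol <- sumInterval(img, iv[1], iv[2])
        ra <- lapply(ids, function(r) regionActivity(vol, fractions, r))
        names(ra) <- ids
        ref <- if (identical(referenceRegion, "whole_voi"))
          regionActivity(vol, fractions, "whole_voi")
        else ra[[as.character(referenceRegion)]]
        refVal <- if (concentrationBasedUR) ref$concentration_Bq_per_mL
                  else ref$activity_Bq
        for (r in ids) {
          num <- if (concentrationBasedUR) ra[[r]]$concentration_Bq_per_mL
                 else ra[[r]]$activity_Bq
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = animal, group = rec$group, state = state,
            region = r,
            interval = sprintf("%g-%g min", iv[1], iv[2]),
            A_N = normalizedActivity(ra[[r]]$activity_Bq,
                                     rec$injected_activity_Bq),
            SUV = suv(ra[[r]]$concentration_Bq_per_mL,
                      rec$injected_activity_Bq, rec$body_weight_g),
            UR = uptakeRatio(num, refVal))
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("QuantResult", table = tab,
      referenceRegion = as.character(referenceRegion))
}

#' Write a QuantResult as tidy CSV
#'
#' Long format: one row per (animal, group, state, region, interval,
#' parameter, value).
#'
#' @param quant a \code{QuantResult}.
#' @param path output CSV path.
#' @param wide also write a wide-format companion (default FALSE).
#' @return \code{path}, invisibly.
#' @export
writeQuantCsv <- function(quant, path, wide = FALSE) {
  tab <- quant@table
  long <- do.call(rbind, lapply(c("A_N", "SUV", "UR"), function(p) {
    data.frame(tab[c("animal_id", "group", "state", "region", "interval")],
               parameter = p, value = tab[[p]])
  }))
  long <- long[order(long$animal_id, long$state, long$region,
                     long$interval, long$parameter), ]
  utils::write.csv(long, path, row.names = FALSE)
  if (wide)
    utils::write.csv(tab, sub("\\.csv$", "_wide.csv", path),
                     row.names = FALSE)
  invisible(path)
}
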