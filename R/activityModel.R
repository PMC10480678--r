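## SUV-based activity painting with 68Ga physical decay.

## physical half-life of 68Ga [min]
.GA68_HALF_LIFE_MIN <- 67.71

#' Physical decay factor of 68Ga
#'
#' `exp(-ln(2) * dt / T_half)` with a default half-life of 67.71 min.
#'
#' @param deltaTMin elapsed time in minutes (>= 0).
#' @param halfLifeMin half-life in minutes.
#' @return decay factor in (0, 1].
#' @export
#' @examples
#' decayFactor(67.71)  # 0.5
#' decayFactor(60)     # ~0.541
decayFactor <- function(deltaTMin, halfLifeMin = .GA68_HALF_LIFE_MIN) {
  if (any(deltaTMin < 0)) stop("elapsed time must be non-negative")
  exp(-log(2) * deltaTMin / halfLifeMin)
}

#' Paint a voxelwise activity distribution onto a phantom
#'
#' Each voxel receives `A_inj * SUV(code) * V_vox / w_T` becquerel, with
#' the injected activity in Bq, the voxel volume in mL, the SUV from the
#' structure table and the total weight `w_T` in grams (so SUV = 1
#' corresponds to the whole-body-average concentration).  Physical decay
#' over the uptake period is then applied unless disabled.
#'
#' @param phantom a [CodePhantom-class].
#' @param table a [StructureTable-class] covering all phantom codes.
#' @param injectedMBq injected activity in MBq.
#' @param uptakeMin minutes between administration and imaging.
#' @param applyDecay apply [decayFactor()] over `uptakeMin`.
#' @param weightKg total weight used as `w_T`; defaults to the phantom's
#'   voxel mass from [computeBodyMetrics()].
#' @param halfLifeMin 68Ga half-life in minutes.
#' @return an [ActivityMap-class].
#' @export
#' @examples
#' ph <- buildPhantom(phantomSpec(1.7, 70, spacing = c(10, 10, 10)))
#' am <- paintActivity(ph, injectedMBq = 140)
#' am
paintActivity <- function(phantom, table = defaultStructureTable(),
                          injectedMBq, uptakeMin = 60, applyDecay = TRUE,
                          weightKg = NULL,
                          halfLifeMin = .GA68_HALF_LIFE_MIN) {
  if (injectedMBq < 0) stop("injected activity must be >= 0")
  if (is.null(weightKg))
    weightKg <- computeBodyMetrics(phantom, table)@weightKg
  suv <- structureSuv(table, phantom@codes)
  vvoxMl <- prod(phantom@spacing) / 1000
  wGrams <- weightKg * 1000
  act <- injectedMBq * 1e6 * suv * vvoxMl / wGrams
  dec <- if (applyDecay) decayFactor(uptakeMin, halfLifeMin) else 1
  methods::new("ActivityMap", data = act * dec, spacing = phantom@spacing,
               injectedMBq = injectedMBq, uptakeMin = uptakeMin,
               decayApplied = applyDecay)
}

#' Fraction of injected activity inside the imaged axial range
#'
#' The activity summed over the phantom's mid-thigh-to-forehead slice
#' interval divided by the injected activity, evaluated at paint time
#' (any recorded physical decay is divided out, since the fraction refers
#' to the initially injected activity).
#'
#' @param activityMap an [ActivityMap-class].
#' @param phantom the [CodePhantom-class] providing the imaged range.
#' @param halfLifeMin 68Ga half-life used to undo recorded decay.
#' @return scalar fraction in `[0, ...)`.
#' @export
computeImagedFraction <- function(activityMap, phantom,
                                  halfLifeMin = .GA68_HALF_LIFE_MIN) {
  stopifnot(all(dim(activityMap@data) == dim(phantom@codes)))
  if (activityMap@injectedMBq == 0) return(0)
  rng <- phantom@imagedRange
  if (rng[1] > dim(activityMap@data)[3] || rng[2] < 1) return(0)
  sel <- max(rng[1], 1L):min(rng[2], dim(activityMap@data)[3])
  tot <- sum(activityMap@data[, , sel])
  if (activityMap@decayApplied)
    tot <- tot / decayFactor(activityMap@uptakeMin, halfLifeMin)
  tot / (activityMap@injectedMBq * 1e6)
}
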