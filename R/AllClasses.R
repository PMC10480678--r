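## S4 classes for the phantom / simulation / metrics chain.

#' CodePhantom: integer-coded voxel phantom
#'
#' A voxelised anatomical scene in which every voxel holds an integer
#' structure code (0 = air outside the body).  Codes are resolved to
#' densities and SUVs through a companion [StructureTable-class].
#'
#' @slot codes integer 3-D array of structure codes (x, y, z; z = axial).
#' @slot spacing numeric(3), voxel edge lengths in mm.
#' @slot heightM body height in m.
#' @slot imagedRange integer(2), axial slice interval corresponding to the
#'   mid-thigh-to-forehead coverage of a whole-body acquisition.
#' @slot name phantom identifier ("P1" ... style).
#' @slot densityScale scalar multiplier applied to the soft-tissue density
#'   when phantom weight is forced to a target value.
#' @slot softTissueCode integer code of generic soft tissue (the structure
#'   affected by `densityScale`).
#' @export
setClass("CodePhantom",
  representation(
    codes = "array",
    spacing = "numeric",
    heightM = "numeric",
    imagedRange = "integer",
    name = "character",
    densityScale = "numeric",
    softTissueCode = "integer"
  ),
  prototype(densityScale = 1, softTissueCode = 1L, name = "phantom")
)

setValidity("CodePhantom", function(object) {
  msg <- NULL
  if (length(dim(object@codes)) != 3L)
    msg <- c(msg, "codes must be a 3-D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values [mm]")
  if (length(object@heightM) != 1L || object@heightM <= 0)
    msg <- c(msg, "height must be a single positive value [m]")
  if (length(object@imagedRange) != 2L ||
      object@imagedRange[1] > object@imagedRange[2])
    msg <- c(msg, "imagedRange must be an increasing slice interval")
  if (any(object@codes < 0))
    msg <- c(msg, "codes must be non-negative (0 = air)")
  if (length(object@densityScale) != 1L || object@densityScale <= 0)
    msg <- c(msg, "densityScale must be a positive scalar")
  if (is.null(msg)) TRUE else msg
})

#' StructureTable: code to (name, density, SUV) lookup
#'
#' Houses the structure lookup used both for material assignment (density,
#' hence the 511 keV attenuation map) and for activity painting (SUV).
#'
#' @slot table data.frame with columns `code`, `name`, `density_g_cm3`,
#'   `suv`.
#' @export
setClass("StructureTable", representation(table = "data.frame"))

setValidity("StructureTable", function(object) {
  tb <- object@table
  need <- c("code", "name", "density_g_cm3", "suv")
  if (!all(need %in% names(tb)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$code)) return("duplicate structure codes")
  body <- tb$code != 0L
  if (any(tb$density_g_cm3[body] <= 0))
    return("body structures must have density > 0")
  if (any(tb$suv < 0)) return("SUV must be >= 0")
  TRUE
})

#' BodyMetrics: candidate body-size parameters of a phantom
#'
#' Weight, BMI, Du Bois body surface area and maximal abdominal
#' circumference -- the candidate predictors for the normalised-SNR
#' power-law fit.
#'
#' @slot weightKg total weight in kg (sum of voxel mass).
#' @slot heightM height in m.
#' @slot bmi body mass index in kg/m^2.
#' @slot bsaM2 Du Bois body surface area in m^2.
#' @slot circumferenceCm maximal axial body-contour perimeter in cm.
#' @export
setClass("BodyMetrics",
  representation(weightKg = "numeric", heightM = "numeric", bmi = "numeric",
                 bsaM2 = "numeric", circumferenceCm = "numeric"))

setValidity("BodyMetrics", function(object) {
  v <- c(object@weightKg, object@heightM, object@bmi, object@bsaM2,
         object@circumferenceCm)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all body metrics must be strictly positive and finite")
  TRUE
})

#' TumourSet: liver tumours grown from random seeds
#'
#' @slot seeds integer matrix (n x 3) of seed voxel indices.
#' @slot frac numeric matrix (n x 3) of fractional positions within the
#'   liver bounding box (used to transfer seeds between phantoms).
#' @slot targetsMl numeric target volumes in mL.
#' @slot realisedMl numeric realised volumes in mL.
#' @slot masks list of integer matrices (voxel indices) per tumour;
#'   pairwise disjoint, all inside the liver.
#' @slot dim integer(3) grid dimension the indices refer to.
#' @export
setClass("TumourSet",
  representation(seeds = "matrix", frac = "matrix", targetsMl = "numeric",
                 realisedMl = "numeric", masks = "list", dim = "integer"))

setValidity("TumourSet", function(object) {
  n <- nrow(object@seeds)
  if (length(object@targetsMl) != n || length(object@masks) != n ||
      length(object@realisedMl) != n)
    return("seed / target / mask counts disagree")
  if (n && (any(object@frac < 0) || any(object@frac > 1)))
    return("fractional coordinates must lie in [0, 1]")
  TRUE
})

#' ActivityMap: per-voxel activity in Bq
#'
#' @slot data numeric 3-D array, activity per voxel in Bq.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot injectedMBq injected activity in MBq.
#' @slot uptakeMin minutes between administration and imaging.
#' @slot decayApplied whether physical decay over the uptake period has
#'   been applied to the voxel values.
#' @export
setClass("ActivityMap",
  representation(data = "array", spacing = "numeric", injectedMBq = "numeric",
                 uptakeMin = "numeric", decayApplied = "logical"))

setValidity("ActivityMap", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
  if (any(object@data < 0)) return("activity must be non-negative")
  if (object@injectedMBq < 0) return("injected activity must be >= 0")
  TRUE
})

#' MuMap: 511 keV linear attenuation coefficients
#'
#' @slot data numeric 3-D array of attenuation coefficients in 1/mm.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @export
setClass("MuMap", representation(data = "array", spacing = "numeric"))

setValidity("MuMap", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
  if (any(object@data < 0)) return("attenuation must be non-negative")
  TRUE
})

#' Sinogram: per-slice projection counts
#'
#' Parallel-beam projection data indexed (radial bin, angle, slice), with
#' the acquisition parameters needed by the reconstruction: time per bed,
#' the detection-sensitivity scalar, and the known uniform background
#' (scatter + randoms surrogate) expectation.
#'
#' @slot counts integer-valued array (nBins, nAngles, nSlices).
#' @slot angles projection angles in radians over `[0, pi)`.
#' @slot tMin acquisition time per bed position in minutes.
#' @slot sensitivity expected detected counts per (Bq voxel) and minute
#'   along one unattenuated projection angle.
#' @slot backgroundFraction fraction of total counts contributed by the
#'   uniform background term.
#' @slot bgPerSlice expected background counts per (bin, angle) cell, one
#'   value per slice; part of the known forward model.
#' @slot seed RNG seed used for the Poisson draw (NA for noiseless data).
#' @export
setClass("Sinogram",
  representation(counts = "array", angles = "numeric", tMin = "numeric",
                 sensitivity = "numeric", backgroundFraction = "numeric",
                 bgPerSlice = "numeric", seed = "integer"))

setValidity("Sinogram", function(object) {
  if (length(dim(object@counts)) != 3L) return("counts must be 3-D")
  if (dim(object@counts)[2] != length(object@angles))
    return("angle count mismatch")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (length(object@bgPerSlice) != dim(object@counts)[3])
    return("bgPerSlice must have one value per slice")
  if (object@tMin <= 0 || object@sensitivity <= 0)
    return("acquisition time and sensitivity must be positive")
  if (object@backgroundFraction < 0 || object@backgroundFraction >= 1)
    return("background fraction must lie in [0, 1)")
  TRUE
})

#' ReconImage: reconstructed activity concentration
#'
#' @slot data numeric 3-D array in Bq/mL.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot iterations,subsets OSEM settings used.
#' @slot fwhmTransMm,fwhmAxMm Gaussian post-filter FWHMs in mm.
#' @export
setClass("ReconImage",
  representation(data = "array", spacing = "numeric", iterations = "integer",
                 subsets = "integer", fwhmTransMm = "numeric",
                 fwhmAxMm = "numeric"))

setValidity("ReconImage", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
  if (any(object@data < 0))
    return("reconstruction must be non-negative (OSEM preserves positivity)")
  TRUE
})

#' PowerLawFit: SNR_Norm = a * p^(-d)
#'
#' Least-squares fit of the normalised liver SNR against a body-size
#' parameter p, with the coefficient of determination used for model
#' selection between candidate parameters.
#'
#' @slot parameter name of the body-size parameter ("weight", "bmi",
#'   "bsa" or "circumference").
#' @slot a,d power-law coefficients.
#' @slot rSquared coefficient of determination on the linear scale.
#' @slot data data.frame with columns `p`, `snrNorm`, `fitted`.
#' @slot logCoef named numeric, the log-log regression coefficients used
#'   for initialisation (diagnostic).
#' @export
setClass("PowerLawFit",
  representation(parameter = "character", a = "numeric", d = "numeric",
                 rSquared = "numeric", data = "data.frame",
                 logCoef = "numeric"))

setValidity("PowerLawFit", function(object) {
  if (object@a <= 0) return("coefficient a must be positive")
  if (object@rSquared > 1 + 1e-12) return("R^2 cannot exceed 1")
  TRUE
})

#' ProtocolSpec: an activity-administration protocol
#'
#' Three kinds are supported: `"fixed"` (a fixed activity for every
#' patient), `"linear_per_kg"` (activity proportional to weight), and
#' `"power_law"` (the constant-SNR prescription derived from a
#' [PowerLawFit-class]).
#'
#' @slot kind one of "fixed", "linear_per_kg", "power_law".
#' @slot params named list of parameters: `A0_MBq` (fixed);
#'   `rate_MBq_per_kg` (linear); `a`, `d`, `parameter`, `snrConst`,
#'   `tMin` (power law).
#' @export
setClass("ProtocolSpec", representation(kind = "character", params = "list"))

setValidity("ProtocolSpec", function(object) {
  kinds <- c("fixed", "linear_per_kg", "power_law")
  if (!object@kind %in% kinds)
    return(sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
  need <- switch(object@kind,
    fixed = "A0_MBq",
    linear_per_kg = "rate_MBq_per_kg",
    power_law = c("a", "d", "parameter", "snrConst", "tMin"))
  if (!all(need %in% names(object@params)))
    return(sprintf("missing protocol parameters: %s",
                   paste(setdiff(need, names(object@params)), collapse = ", ")))
  TRUE
})

#' NemaResult: per-sphere NEMA SNR and CNR
#'
#' @slot table data.frame with one row per sphere diameter: `diameter_mm`,
#'   `bg_mean`, `bg_sd`, `sphere_mean`, `snr`, `cnr`.
#' @slot nBackgroundRois number of background ROIs per diameter (60).
#' @export
setClass("NemaResult",
  representation(table = "data.frame", nBackgroundRois = "integer"))
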