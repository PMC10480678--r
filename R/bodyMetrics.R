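## Body-size metrics: the candidate predictors for the power-law fit.

#' Du Bois body surface area
#'
#' `BSA = 0.007184 * W^0.425 * H_cm^0.725` with weight in kg and height in
#' cm.
#'
#' @param weightKg weight in kg.
#' @param heightM height in m.
#' @return BSA in m^2.
#' @export
#' @examples
#' duBoisBsa(56, 1.73)  # 1.67 m^2
duBoisBsa <- function(weightKg, heightM) {
  stopifnot(all(weightKg > 0), all(heightM > 0))
  0.007184 * weightKg^0.425 * (heightM * 100)^0.725
}

#' Body mass index
#'
#' @inheritParams duBoisBsa
#' @return BMI in kg/m^2.
#' @export
bodyMassIndex <- function(weightKg, heightM) {
  stopifnot(all(weightKg > 0), all(heightM > 0))
  weightKg / heightM^2
}

#' Compute body-size metrics of a phantom
#'
#' Weight is the voxel mass sum (density times voxel volume, honouring a
#' forced-weight density scale); BMI and Du Bois BSA follow from the
#' stored height; abdominal circumference is the maximum over axial slices
#' of the body-contour perimeter.
#'
#' @param phantom a [CodePhantom-class].
#' @param table a [StructureTable-class] covering all phantom codes.
#' @return a [BodyMetrics-class].
#' @export
#' @examples
#' ph <- buildPhantom(phantomSpec(1.73, 56, spacing = c(8, 8, 8),
#'                                organs = FALSE))
#' computeBodyMetrics(ph)
computeBodyMetrics <- function(phantom, table = defaultStructureTable()) {
  codes <- phantom@codes
  if (!any(codes > 0L)) stop("phantom has an empty body mask")
  vvoxMl <- prod(phantom@spacing) / 1000
  dens <- phantomDensity(phantom, table)
  weightKg <- sum(dens) * vvoxMl / 1000
  h <- phantom@heightM
  bmi <- bodyMassIndex(weightKg, h)
  bsa <- duBoisBsa(weightKg, h)
  circ <- maxBodyCircumferenceMm(codes > 0L, phantom@spacing) / 10
  methods::new("BodyMetrics", weightKg = weightKg, heightM = h, bmi = bmi,
               bsaM2 = bsa, circumferenceCm = circ)
}

## Maximum over axial slices of the largest closed body contour [mm].
## All slices are searched; the abdomen dominates when the torso is the
## widest region, as in the default anatomy.
maxBodyCircumferenceMm <- function(mask, spacing) {
  nz <- dim(mask)[3]
  best <- 0
  for (k in seq_len(nz)) {
    sl <- mask[, , k]
    if (!any(sl)) next
    ## cheap upper bound: a slice whose bounding box is far smaller than
    ## the current best cannot win (perimeter <= 2 * (w + h) of the box)
    rs <- range(which(rowSums(sl) > 0)); cs <- range(which(colSums(sl) > 0))
    ub <- 2 * ((rs[2] - rs[1] + 2) * spacing[1] + (cs[2] - cs[1] + 2) * spacing[2])
    if (ub <= best) next
    p <- maskPerimeterMm(sl, spacing[1:2])
    if (p > best) best <- p
  }
  if (best <= 0) stop("no body contour found")
  best
}
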