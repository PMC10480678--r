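## Image-quality metrics: liver SNR, tumour-to-liver CNR, Rose criterion.
## All standard deviations are population SDs (divisor N) -- the single
## convention used throughout the package.

#' Distance to the nearest voxel outside a mask
#'
#' Exact Euclidean distance transform with anisotropic spacing: for every
#' voxel, the physical distance to the nearest voxel centre where `mask`
#' is `FALSE`.
#'
#' @param mask logical 3-D array.
#' @param spacing voxel spacing in mm.
#' @return numeric array of distances in mm (`Inf` where no outside voxel
#'   exists).
#' @export
distanceToOutside <- function(mask, spacing) {
  d <- cpp_edt(as.logical(!mask), as.integer(dim(mask)), as.double(spacing))
  array(d, dim(mask))
}

#' Place the spherical liver VOI
#'
#' The VOI centre is the liver voxel maximising the distance to the
#' nearest non-liver or tumour voxel (i.e. the centre of the largest
#' sphere fitting in tumour-free liver), with a deterministic tie-break
#' towards the lowest (z, y, x) index.  This operationalises "a uniform
#' part of the liver".
#'
#' @param liverMask logical 3-D array (tumour voxels excluded or not;
#'   they are excluded via `tumours` either way).
#' @param spacing voxel spacing in mm.
#' @param tumours a [TumourSet-class] or `NULL`.
#' @param diameterMm VOI diameter in mm (default 25).
#' @return list with `mask` (logical array), `centre` (voxel index) and
#'   `radiusMm`.
#' @export
placeLiverVoi <- function(liverMask, spacing, tumours = NULL,
                          diameterMm = 25) {
  if (!any(liverMask)) stop("liver mask is empty")
  free <- liverMask
  if (!is.null(tumours))
    for (m in tumours@masks) free[m] <- FALSE
  d <- distanceToOutside(free, spacing)
  d[!free] <- -Inf
  r <- diameterMm / 2
  best <- max(d)
  if (best + 0.5 * min(spacing) < r)
    stop(sprintf(
      "liver cannot contain a %.0f mm VOI clear of tumours (max clearance %.1f mm)",
      diameterMm, best))
  cand <- if (is.finite(best)) maskIndices(d >= best - 1e-9) else
    maskIndices(is.infinite(d) & free)
  ord <- order(cand[, 3], cand[, 2], cand[, 1])
  centre <- cand[ord[1], ]
  ball <- ballMask(dim(liverMask), spacing, centre, diameterMm)
  ball <- ball & free
  list(mask = ball, centre = centre, radiusMm = r)
}

#' Liver signal-to-noise ratio
#'
#' `SNR_L = mean(VOI) / sd(VOI)` with the population SD over the VOI
#' voxels.
#'
#' @param image a [ReconImage-class] or numeric 3-D array.
#' @param voi VOI as returned by [placeLiverVoi()] (or a logical array).
#' @return scalar SNR.
#' @export
liverSnr <- function(image, voi) {
  vals <- .voiValues(image, voi)
  s <- popSd(vals)
  if (s == 0) stop("degenerate VOI: zero standard deviation")
  mean(vals) / s
}

#' Tumour-to-liver contrast-to-noise ratio
#'
#' `CNR = (mean(tumour) - mean(VOI)) / sd(VOI)`, evaluated over the true
#' (painted) tumour mask, with the Rose-criterion classification
#' `CNR >= 5` (inclusive).
#'
#' @param image a [ReconImage-class] or numeric 3-D array.
#' @param tumourMask logical array or n x 3 voxel index matrix.
#' @param voi VOI as returned by [placeLiverVoi()] (or a logical array).
#' @param roseThreshold detectability threshold on CNR.
#' @return list with `cnr` and `rosePass`.
#' @export
tumourCnr <- function(image, tumourMask, voi, roseThreshold = 5) {
  vals <- .voiValues(image, voi)
  s <- popSd(vals)
  if (s == 0) stop("degenerate VOI: zero standard deviation")
  img <- if (methods::is(image, "ReconImage")) image@data else image
  tvals <- img[tumourMask]
  if (!length(tvals)) stop("empty tumour mask")
  cnr <- (mean(tvals) - mean(vals)) / s
  list(cnr = cnr, rosePass = cnr >= roseThreshold)
}

.voiValues <- function(image, voi) {
  img <- if (methods::is(image, "ReconImage")) image@data else image
  mask <- if (is.list(voi)) voi$mask else voi
  vals <- img[mask]
  if (!length(vals)) stop("empty VOI")
  vals
}
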