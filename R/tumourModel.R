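## Liver tumour model: random seeds, spherical growth to target volumes,
## relative-position reuse across phantoms.

## the eight default target volumes [mL]
.TUMOUR_VOLUMES_ML <- c(0.15, 0.40, 0.69, 1.68, 2.56, 3.72, 5.34, 8.09)

#' Default tumour target volumes
#'
#' The eight liver tumour volumes grown in every phantom, in mL.
#' @return numeric(8).
#' @export
tumourTargetVolumesMl <- function() .TUMOUR_VOLUMES_ML

#' Randomly place tumour seeds inside a liver mask
#'
#' Seeds are drawn uniformly from liver voxels at least `marginMm` from
#' the liver boundary and at pairwise physical separation of at least
#' `minSeparationMm`.  The draw is a deterministic function of `rngSeed`.
#' Fractional positions within the liver's axis-aligned bounding box are
#' recorded so seeds can be transferred between phantoms.
#'
#' @param liverMask logical 3-D array.
#' @param spacing voxel spacing in mm.
#' @param n number of seeds.
#' @param minSeparationMm minimum pairwise seed separation in mm.
#' @param marginMm minimum distance from the liver boundary in mm.
#' @param rngSeed integer seed.
#' @return list with `seeds` (n x 3 voxel indices) and `frac` (n x 3
#'   fractional bounding-box coordinates).
#' @export
placeSeeds <- function(liverMask, spacing, n = 8, minSeparationMm = 15,
                       marginMm = 10, rngSeed = 1L) {
  if (!any(liverMask)) stop("liver mask is empty")
  if (marginMm > 0) {
    ## distance from the voxel centre to the nearest outside-liver voxel
    ## centre, offset by half a voxel, approximates the boundary distance
    dOut <- distanceToOutside(liverMask, spacing)
    eligible <- liverMask & (dOut - 0.5 * min(spacing) >= marginMm)
  } else eligible <- liverMask
  idx <- maskIndices(eligible)
  if (nrow(idx) < n)
    stop(sprintf("only %d eligible liver voxels for %d seeds", nrow(idx), n))
  pos <- voxelCentresMm(idx, spacing)
  sel <- withSeed(rngSeed, {
    ord <- sample.int(nrow(idx))
    keep <- integer(0)
    for (i in ord) {
      if (!length(keep)) { keep <- i }
      else {
        d <- sqrt(colSums((t(pos[keep, , drop = FALSE]) - pos[i, ])^2))
        if (min(d) >= minSeparationMm) keep <- c(keep, i)
      }
      if (length(keep) == n) break
    }
    keep
  })
  if (length(sel) < n)
    stop(sprintf("seed constraints unsatisfiable: placed %d of %d seeds",
                 length(sel), n))
  seeds <- idx[sel, , drop = FALSE]
  list(seeds = seeds, frac = .bboxFraction(seeds, liverMask))
}

## fractional coordinates of voxel indices within a mask's bounding box
.bboxFraction <- function(seeds, mask) {
  idx <- maskIndices(mask)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  span <- pmax(hi - lo, 1L)
  fr <- sweep(sweep(seeds, 2, lo, "-"), 2, span, "/")
  fr[, span == 0] <- 0.5
  pmin(pmax(fr, 0), 1)
}

#' Transfer tumour seeds between livers by relative position
#'
#' Each seed's fractional coordinates within the source liver's bounding
#' box are mapped into the target liver's bounding box and snapped to the
#' nearest liver voxel (physical distance).
#'
#' @param frac n x 3 matrix of fractional coordinates (from
#'   [placeSeeds()]).
#' @param targetLiverMask logical 3-D array of the target liver.
#' @param spacing voxel spacing of the target grid in mm.
#' @return list with `seeds` and `frac` for the target liver.
#' @export
transferSeeds <- function(frac, targetLiverMask, spacing) {
  idx <- maskIndices(targetLiverMask)
  if (nrow(idx) == 0L) stop("target liver mask is empty")
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  span <- pmax(hi - lo, 1L)
  cand <- sweep(sweep(frac, 2, span, "*"), 2, lo, "+")
  pos <- voxelCentresMm(idx, spacing)
  seeds <- t(apply(cand, 1, function(p) {
    pmm <- (p - 0.5) * spacing
    d2 <- colSums((t(pos) - pmm)^2)
    idx[which.min(d2), ]
  }))
  list(seeds = seeds, frac = .bboxFraction(seeds, targetLiverMask))
}

#' Grow a tumour spherically to a target volume
#'
#' The mask consists of the `n = round(target / V_vox)` liver voxels
#' nearest the seed centre by physical distance (ties broken by
#' lexicographic z, y, x index), so the realised volume differs from the
#' target by at most half a voxel volume when the sphere is not clipped by
#' the liver boundary.
#'
#' @param liverMask logical 3-D array of eligible voxels (liver minus
#'   voxels already claimed by other tumours).
#' @param spacing voxel spacing in mm.
#' @param seed integer(3) seed voxel index.
#' @param targetVolumeMl target volume in mL.
#' @return integer matrix of voxel indices (n x 3).
#' @export
growTumour <- function(liverMask, spacing, seed, targetVolumeMl) {
  vvox <- prod(spacing) / 1000
  if (targetVolumeMl < vvox / 2)
    stop(sprintf("target volume %.4f mL is below half a voxel (%.4f mL)",
                 targetVolumeMl, vvox))
  n <- round(targetVolumeMl / vvox)
  idx <- maskIndices(liverMask)
  if (nrow(idx) < n)
    stop("liver mask too small for requested tumour volume")
  centre <- (seed - 0.5) * spacing
  d2 <- colSums((t(voxelCentresMm(idx, spacing)) - centre)^2)
  ord <- order(d2, idx[, 3], idx[, 2], idx[, 1])
  idx[ord[seq_len(n)], , drop = FALSE]
}

#' Seed and grow the full tumour set of a phantom
#'
#' Places (or transfers) seeds and grows the eight default tumours in
#' index order; later tumours exclude voxels already claimed by earlier
#' ones.
#'
#' @param liverMask logical 3-D array.
#' @param spacing voxel spacing in mm.
#' @param targetsMl target volumes in mL.
#' @param rngSeed integer seed for the placement draw.
#' @param seedInfo optional list with `seeds`/`frac` (e.g. from
#'   [transferSeeds()]); when supplied no random placement is performed.
#' @param minSeparationMm,marginMm placement constraints passed to
#'   [placeSeeds()].
#' @return a [TumourSet-class].
#' @export
buildTumourSet <- function(liverMask, spacing,
                           targetsMl = tumourTargetVolumesMl(),
                           rngSeed = 1L, seedInfo = NULL,
                           minSeparationMm = 15, marginMm = 10) {
  if (is.null(seedInfo))
    seedInfo <- placeSeeds(liverMask, spacing, n = length(targetsMl),
                           minSeparationMm = minSeparationMm,
                           marginMm = marginMm, rngSeed = rngSeed)
  vvox <- prod(spacing) / 1000
  avail <- liverMask
  masks <- vector("list", length(targetsMl))
  for (i in seq_along(targetsMl)) {
    m <- growTumour(avail, spacing, seedInfo$seeds[i, ], targetsMl[i])
    masks[[i]] <- m
    avail[m] <- FALSE
  }
  methods::new("TumourSet",
               seeds = seedInfo$seeds, frac = seedInfo$frac,
               targetsMl = targetsMl,
               realisedMl = vapply(masks, nrow, integer(1)) * vvox,
               masks = masks, dim = dim(liverMask))
}

#' Stamp a tumour set into a phantom
#'
#' Tumour voxels overwrite the liver code with the tumour code (tumours
#' are a structure with their own density and SUV).
#'
#' @param phantom a [CodePhantom-class].
#' @param tumours a [TumourSet-class] on the same grid.
#' @param code tumour structure code.
#' @return the modified [CodePhantom-class].
#' @export
addTumours <- function(phantom, tumours, code = structureCode("tumours")) {
  stopifnot(all(tumours@dim == dim(phantom@codes)))
  codes <- phantom@codes
  for (m in tumours@masks) codes[m] <- as.integer(code)
  phantom@codes <- codes
  phantom
}

#' Label volume of a tumour set
#'
#' @param tumours a [TumourSet-class].
#' @return integer array with tumour index per voxel (0 elsewhere).
#' @export
tumourLabelVolume <- function(tumours) {
  lab <- array(0L, tumours@dim)
  for (i in seq_along(tumours@masks)) lab[tumours@masks[[i]]] <- i
  lab
}
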