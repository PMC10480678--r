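## Desk-scale PET acquisition model: attenuated parallel-beam forward
## projection of the activity map, Poisson count sampling, and a uniform
## additive background standing in for scatter + randoms.

## 511 keV linear attenuation coefficient of water [1/mm]
.MU_WATER_511 <- 0.0096

#' 511 keV attenuation map of a phantom
#'
#' `mu = mu_water(511 keV) * density / 1 g/cm^3`, with
#' `mu_water = 0.0096 / mm`.
#'
#' @param phantom a [CodePhantom-class].
#' @param table a [StructureTable-class].
#' @param muWater attenuation coefficient of water at 511 keV in 1/mm.
#' @return a [MuMap-class].
#' @export
attenuationMap <- function(phantom, table = defaultStructureTable(),
                           muWater = .MU_WATER_511) {
  dens <- phantomDensity(phantom, table)
  methods::new("MuMap", data = dens * muWater, spacing = phantom@spacing)
}

#' Projection angles over half a turn
#'
#' @param nAngles number of evenly spaced angles over `[0, pi)`.
#' @return numeric vector of angles in radians.
#' @export
projectionAngles <- function(nAngles = 192) {
  stopifnot(nAngles >= 1)
  seq(0, pi, length.out = nAngles + 1)[seq_len(nAngles)]
}

## default radial bin count for an nx x ny slice (covers the diagonal)
defaultBinCount <- function(nx, ny) {
  as.integer(2L * ceiling(sqrt(nx^2 + ny^2) / 2) + 3L)
}

#' Parallel-beam forward projection (stack of axial slices)
#'
#' Pixel-driven splatting at one radial bin per voxel pitch; the bin sums
#' of each angle equal the slice sum (mass conservation), and multiplying
#' by the voxel pitch approximates line integrals.
#'
#' @param vol numeric 3-D array (x, y, z).
#' @param angles projection angles in radians.
#' @param nBins number of radial bins.
#' @return numeric array (nBins, nAngles, nSlices).
#' @export
radonTransform <- function(vol, angles = projectionAngles(),
                           nBins = defaultBinCount(dim(vol)[1], dim(vol)[2])) {
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  cpp_project(as.double(vol), d[1], d[2], d[3],
              cos(angles), sin(angles), as.integer(nBins))
}

#' Adjoint of [radonTransform()]
#'
#' @param sino numeric array (nBins, nAngles, nSlices).
#' @param nx,ny in-plane output dimensions.
#' @param angles projection angles in radians.
#' @return numeric 3-D array (nx, ny, nSlices).
#' @export
backProject <- function(sino, nx, ny, angles = projectionAngles()) {
  d <- dim(sino)
  stopifnot(length(d) == 3L, d[2] == length(angles))
  cpp_backproject(as.double(sino), as.integer(nx), as.integer(ny), d[3],
                  cos(angles), sin(angles), d[1])
}

#' Simulate a noisy PET acquisition
#'
#' The expected sinogram is
#' `lambda = s * t * Radon(activity) * exp(-Radon(mu))` plus a uniform
#' background whose expected counts make up fraction `b` of the total
#' (the scatter + randoms surrogate, treated as known by the
#' reconstruction).  Counts are drawn as Poisson variates, reproducibly
#' for a given `rngSeed`; with `noise = FALSE` the expectation itself is
#' returned.
#'
#' @param activity an [ActivityMap-class].
#' @param mu a [MuMap-class] on the same grid.
#' @param tMin acquisition time per bed position in minutes.
#' @param sensitivity expected detected counts per Bq-minute and angle
#'   for an unattenuated source.
#' @param backgroundFraction fraction `b` in `[0, 1)` of total counts
#'   contributed by the uniform background.
#' @param rngSeed integer seed for the Poisson draw; each slice uses a
#'   sub-seed derived from it, so a slice's counts do not depend on which
#'   other slices are simulated.
#' @param angles projection angles.
#' @param nBins number of radial bins.
#' @param noise draw Poisson counts (TRUE) or return the expectation.
#' @return a [Sinogram-class].
#' @export
simulateCounts <- function(activity, mu, tMin = 3, sensitivity = 1e-4,
                           backgroundFraction = 0.3, rngSeed = 1L,
                           angles = projectionAngles(),
                           nBins = defaultBinCount(dim(activity@data)[1],
                                                   dim(activity@data)[2]),
                           noise = TRUE) {
  if (!all(dim(activity@data) == dim(mu@data)))
    stop("activity and attenuation grids do not match")
  if (tMin <= 0 || sensitivity <= 0)
    stop("acquisition time and sensitivity must be positive")
  if (backgroundFraction < 0 || backgroundFraction >= 1)
    stop("background fraction must lie in [0, 1)")
  d <- dim(activity@data)
  proj <- radonTransform(activity@data, angles, nBins)
  attn <- attenuationFactors(mu, angles, nBins)
  trues <- sensitivity * tMin * proj * attn
  nCells <- nBins * length(angles)
  truesPerSlice <- apply(trues, 3, sum)
  b <- backgroundFraction
  bgPerSlice <- if (b > 0) b / (1 - b) * truesPerSlice / nCells else
    rep(0, d[3])
  lambda <- trues + rep(bgPerSlice, each = nCells)
  counts <- if (noise) .poissonBySlice(lambda, rngSeed) else lambda
  methods::new("Sinogram", counts = counts, angles = angles, tMin = tMin,
               sensitivity = sensitivity, backgroundFraction = b,
               bgPerSlice = bgPerSlice,
               seed = if (noise) as.integer(rngSeed) else NA_integer_)
}

#' Attenuation factors `exp(-Radon(mu))` per sinogram cell
#'
#' @param mu a [MuMap-class].
#' @param angles projection angles.
#' @param nBins number of radial bins.
#' @return numeric array (nBins, nAngles, nSlices) of transmission
#'   factors in `(0, 1]`.
#' @export
attenuationFactors <- function(mu, angles = projectionAngles(),
                               nBins = defaultBinCount(dim(mu@data)[1],
                                                       dim(mu@data)[2])) {
  ## line integral ~ splat sum * voxel pitch (isotropic in-plane assumed)
  pitch <- mu@spacing[1]
  exp(-radonTransform(mu@data, angles, nBins) * pitch)
}

## Poisson draw with one derived seed per slice, so any axial sub-window
## of a simulation reproduces the identical counts for those slices.
.poissonBySlice <- function(lambda, rngSeed) {
  d <- dim(lambda)
  out <- array(0, d)
  for (k in seq_len(d[3])) {
    lam <- lambda[, , k]
    out[, , k] <- withSeed(childSeed(rngSeed, "slice", k),
                           stats::rpois(length(lam), lam))
  }
  out
}
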