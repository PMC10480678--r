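## OSEM reconstruction with attenuation correction and Gaussian
## post-filtering.

#' Reconstruct a sinogram with ordered-subsets EM
#'
#' OSEM with the attenuation factors and the known uniform background in
#' the forward model (so the image is corrected for attenuation, scatter
#' and randoms as modelled), followed by conversion to activity
#' concentration (Bq/mL) and an anisotropic Gaussian post-filter.
#'
#' @param sinogram a [Sinogram-class].
#' @param mu the [MuMap-class] used for the acquisition.
#' @param iterations number of OSEM iterations.
#' @param subsets number of ordered subsets; must divide the angle count.
#' @param fwhmTransMm,fwhmAxMm post-filter FWHM in mm (transaxial /
#'   axial); set to 0 to disable.
#' @param postFilter apply the Gaussian post-filter.
#' @param support optional in-plane logical mask (nx x ny): the
#'   reconstruction support (e.g. the dilated body cross-section);
#'   voxels outside it are fixed at 0.
#' @param attn optional precomputed [attenuationFactors()] array for the
#'   sinogram geometry (avoids recomputation in repeated runs).
#' @return a [ReconImage-class].
#' @export
reconstructOSEM <- function(sinogram, mu, iterations = 3, subsets = 16,
                            fwhmTransMm = 5.5, fwhmAxMm = 4,
                            postFilter = TRUE, support = NULL,
                            attn = NULL) {
  d <- dim(sinogram@counts)
  dm <- dim(mu@data)
  if (d[3] != dm[3])
    stop("sinogram and attenuation map slice counts differ")
  nA <- length(sinogram@angles)
  if (nA %% subsets != 0)
    stop(sprintf("subsets (%d) must divide the angle count (%d)",
                 subsets, nA))
  if (is.null(attn))
    attn <- attenuationFactors(mu, sinogram@angles, d[1])
  if (is.null(support))
    support <- matrix(TRUE, dm[1], dm[2])
  st <- sinogram@sensitivity * sinogram@tMin
  x <- cpp_osem_fast(as.double(sinogram@counts), as.double(attn),
                     as.double(sinogram@bgPerSlice),
                     cos(sinogram@angles), sin(sinogram@angles),
                     dm[1], dm[2], dm[3], d[1],
                     as.integer(iterations), as.integer(subsets), st,
                     as.logical(support))
  ## voxel estimate is in Bq per voxel; convert to concentration
  vvoxMl <- prod(mu@spacing) / 1000
  img <- array(x, dm) / vvoxMl
  if (postFilter && (fwhmTransMm > 0 || fwhmAxMm > 0))
    img <- gaussianFilter3d(img, c(fwhmTransMm, fwhmTransMm, fwhmAxMm),
                            mu@spacing)
  img[img < 0] <- 0
  methods::new("ReconImage", data = img, spacing = mu@spacing,
               iterations = as.integer(iterations),
               subsets = as.integer(subsets),
               fwhmTransMm = fwhmTransMm, fwhmAxMm = fwhmAxMm)
}
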