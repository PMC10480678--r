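## NIfTI + JSON-sidecar serialisation of the volume classes and CSV/JSON
## emission of results.

#' Write / read a phantom as NIfTI with a JSON sidecar
#'
#' The code image is stored as an integer NIfTI volume with the voxel
#' spacing in its header; height, name, imaged range and the
#' forced-weight density scale travel in a JSON sidecar next to it.
#'
#' @param phantom a [CodePhantom-class].
#' @param path output path (".nii" or ".nii.gz"); the sidecar gets the
#'   extension ".json".
#' @return `writePhantom` returns `path` invisibly; `readPhantom` the
#'   [CodePhantom-class].
#' @export
writePhantom <- function(phantom, path) {
  img <- RNifti::asNifti(phantom@codes)
  RNifti::pixdim(img) <- phantom@spacing
  RNifti::writeNifti(img, path)
  side <- list(name = phantom@name, height_m = phantom@heightM,
               imaged_range = phantom@imagedRange,
               density_scale = phantom@densityScale,
               soft_tissue_code = phantom@softTissueCode,
               spacing_mm = phantom@spacing)
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writePhantom
#' @export
readPhantom <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  codes <- array(as.integer(img), dim(img))
  methods::new("CodePhantom", codes = codes,
               spacing = as.numeric(side$spacing_mm),
               heightM = side$height_m,
               imagedRange = as.integer(side$imaged_range),
               name = side$name, densityScale = side$density_scale,
               softTissueCode = as.integer(side$soft_tissue_code))
}

.sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write an activity map, sinogram or reconstruction as NIfTI
#'
#' A [Sinogram-class] is stored as its (bin, angle, slice) count array
#' with the acquisition parameters in the sidecar.
#'
#' @param x an [ActivityMap-class], [Sinogram-class] or
#'   [ReconImage-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  if (methods::is(x, "Sinogram")) {
    img <- RNifti::asNifti(x@counts)
    RNifti::writeNifti(img, path)
    side <- list(type = "sinogram_counts", t_min = x@tMin,
                 sensitivity = x@sensitivity,
                 background_fraction = x@backgroundFraction,
                 bg_per_slice = x@bgPerSlice, angles_rad = x@angles,
                 seed = x@seed)
    jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                         digits = NA)
    return(invisible(path))
  }
  sp <- x@spacing
  img <- RNifti::asNifti(x@data)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  side <- if (methods::is(x, "ActivityMap"))
    list(type = "activity_bq_per_voxel", injected_MBq = x@injectedMBq,
         uptake_min = x@uptakeMin, decay_applied = x@decayApplied,
         spacing_mm = sp)
  else
    list(type = "recon_bq_per_ml", iterations = x@iterations,
         subsets = x@subsets, fwhm_trans_mm = x@fwhmTransMm,
         fwhm_ax_mm = x@fwhmAxMm, spacing_mm = sp)
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Serialise a tumour set as CSV
#'
#' One row per tumour: index, target and realised volume, seed voxel and
#' fractional liver-bounding-box coordinates.
#'
#' @param tumours a [TumourSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTumourSet <- function(tumours, path) {
  df <- data.frame(index = seq_along(tumours@targetsMl),
                   target_mL = tumours@targetsMl,
                   realised_mL = tumours@realisedMl,
                   seed_x = tumours@seeds[, 1], seed_y = tumours@seeds[, 2],
                   seed_z = tumours@seeds[, 3],
                   frac_x = tumours@frac[, 1], frac_y = tumours@frac[, 2],
                   frac_z = tumours@frac[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise fits and prescriptions as JSON
#'
#' @param experiment result of [runExperiment()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeExperimentJson <- function(experiment, path) {
  fits <- lapply(experiment$fits, function(f)
    list(parameter = f@parameter, a = f@a, d = f@d,
         r_squared = f@rSquared))
  snr <- experiment$results[experiment$results$metric == "SNR_L", ]
  out <- list(selected_parameter = experiment$bestFit@parameter,
              fits = fits, sensitivity = experiment$sensitivity,
              summary = experiment$summary,
              activities_MBq = split(snr$A_inj_MBq, snr$protocol))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
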