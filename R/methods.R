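#' @include AllClasses.R AllGenerics.R
NULL

## ---- voxel accessors -------------------------------------------------------

#' @rdname voxel-accessors
setMethod("voxelData", "CodePhantom", function(x) x@codes)
#' @rdname voxel-accessors
setMethod("voxelData", "ActivityMap", function(x) x@data)
#' @rdname voxel-accessors
setMethod("voxelData", "MuMap", function(x) x@data)
#' @rdname voxel-accessors
setMethod("voxelData", "ReconImage", function(x) x@data)

for (cl in c("CodePhantom", "ActivityMap", "MuMap", "ReconImage")) {
  setMethod("voxelSpacing", cl, function(x) x@spacing)
  setMethod("voxelVolumeMm3", cl, function(x) prod(x@spacing))
  setMethod("voxelVolumeMl", cl, function(x) prod(x@spacing) / 1000)
}

## ---- phantom accessors -----------------------------------------------------

#' @rdname phantom-accessors
setMethod("phantomName", "CodePhantom", function(x) x@name)
#' @rdname phantom-accessors
setMethod("bodyHeight", "CodePhantom", function(x) x@heightM)
#' @rdname phantom-accessors
setMethod("imagedRange", "CodePhantom", function(x) x@imagedRange)
#' @rdname phantom-accessors
setMethod("bodyMask", "CodePhantom", function(x) x@codes > 0L)
#' @rdname phantom-accessors
setMethod("structureMask", "CodePhantom",
          function(x, code) x@codes == as.integer(code))

## ---- show methods ----------------------------------------------------------

setMethod("show", "CodePhantom", function(object) {
  d <- dim(object@codes)
  cat(sprintf("CodePhantom \"%s\": %d x %d x %d voxels @ %.2f x %.2f x %.2f mm\n",
              object@name, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  height %.2f m, %d body voxels, imaged slices [%d, %d]\n",
              object@heightM, sum(object@codes > 0L),
              object@imagedRange[1], object@imagedRange[2]))
  cat(sprintf("  structure codes present: %s\n",
              paste(sort(unique(as.vector(object@codes))), collapse = " ")))
})

setMethod("show", "StructureTable", function(object) {
  cat(sprintf("StructureTable with %d structures\n", nrow(object@table)))
  print(object@table, row.names = FALSE)
})

setMethod("show", "BodyMetrics", function(object) {
  cat(sprintf(paste0("BodyMetrics: weight %.1f kg, height %.2f m, ",
                     "BMI %.1f kg/m^2,\n  BSA %.2f m^2 (Du Bois), ",
                     "abdominal circumference %.1f cm\n"),
              object@weightKg, object@heightM, object@bmi, object@bsaM2,
              object@circumferenceCm))
})

setMethod("show", "TumourSet", function(object) {
  cat(sprintf("TumourSet with %d tumours\n", nrow(object@seeds)))
  if (nrow(object@seeds)) {
    df <- data.frame(index = seq_len(nrow(object@seeds)),
                     target_mL = object@targetsMl,
                     realised_mL = round(object@realisedMl, 4),
                     voxels = vapply(object@masks, nrow, integer(1)))
    print(df, row.names = FALSE)
  }
})

setMethod("show", "ActivityMap", function(object) {
  cat(sprintf(paste0("ActivityMap: %s voxels, injected %.1f MBq, ",
                     "uptake %.0f min (decay %s)\n  total in map: %.3g MBq\n"),
              paste(dim(object@data), collapse = " x "), object@injectedMBq,
              object@uptakeMin,
              if (object@decayApplied) "applied" else "not applied",
              sum(object@data) / 1e6))
})

setMethod("show", "Sinogram", function(object) {
  d <- dim(object@counts)
  cat(sprintf(paste0("Sinogram: %d bins x %d angles x %d slices, ",
                     "t = %.1f min\n  %.3g counts total, ",
                     "background fraction %.2f\n"),
              d[1], d[2], d[3], object@tMin, sum(object@counts),
              object@backgroundFraction))
})

setMethod("show", "ReconImage", function(object) {
  cat(sprintf(paste0("ReconImage: %s voxels [Bq/mL], OSEM %d it x %d subsets, ",
                     "post-filter %.1f/%.1f mm FWHM\n"),
              paste(dim(object@data), collapse = " x "), object@iterations,
              object@subsets, object@fwhmTransMm, object@fwhmAxMm))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: SNR_Norm = %.4g * %s^(-%.4g), R^2 = %.4f (n = %d)\n",
              object@a, object@parameter, object@d, object@rSquared,
              nrow(object@data)))
})

setMethod("show", "ProtocolSpec", function(object) {
  p <- object@params
  desc <- switch(object@kind,
    fixed = sprintf("fixed %.0f MBq", p$A0_MBq),
    linear_per_kg = sprintf("%.1f MBq/kg of body weight", p$rate_MBq_per_kg),
    power_law = sprintf(
      "constant-SNR: A = (1/t) (SNR^2/a^2) p^(2d), a = %.4g, d = %.4g, p = %s, SNR = %.1f, t = %.0f min",
      p$a, p$d, p$parameter, p$snrConst, p$tMin))
  cat(sprintf("ProtocolSpec [%s]: %s\n", object@kind, desc))
})

setMethod("show", "NemaResult", function(object) {
  cat(sprintf("NemaResult (%d background ROIs per diameter)\n",
              object@nBackgroundRois))
  print(object@table, row.names = FALSE)
})
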