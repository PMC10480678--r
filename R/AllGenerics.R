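#' @include AllClasses.R
NULL

#' Voxel data accessors
#'
#' Accessors shared by the voxelised volume classes
#' ([CodePhantom-class], [ActivityMap-class], [MuMap-class],
#' [ReconImage-class]): the raw 3-D array, the voxel spacing in mm, and the
#' voxel volume.
#'
#' @param x a voxel volume object.
#' @return `voxelData` returns the 3-D array; `voxelSpacing` the numeric
#'   length-3 spacing (x, y, z) in mm; `voxelVolumeMm3` / `voxelVolumeMl`
#'   the volume of a single voxel in mm^3 / mL.
#' @name voxel-accessors
#' @aliases voxelData voxelSpacing voxelVolumeMm3 voxelVolumeMl
#' @examples
#' ph <- buildPhantom(phantomSpec(heightM = 1.7, weightKg = 70,
#'                                spacing = c(12, 12, 12)))
#' dim(voxelData(ph))
#' voxelVolumeMl(ph)
NULL

#' @rdname voxel-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxel-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxel-accessors
#' @export
setGeneric("voxelVolumeMm3", function(x) standardGeneric("voxelVolumeMm3"))

#' @rdname voxel-accessors
#' @export
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))

#' Phantom accessors
#'
#' @param x a [CodePhantom-class].
#' @return `phantomName` the identifier; `bodyHeight` the height in m;
#'   `imagedRange` the axial slice interval (mid-thigh to forehead);
#'   `bodyMask` a logical array marking voxels inside the body.
#' @name phantom-accessors
#' @aliases phantomName bodyHeight imagedRange bodyMask
NULL

#' @rdname phantom-accessors
#' @export
setGeneric("phantomName", function(x) standardGeneric("phantomName"))

#' @rdname phantom-accessors
#' @export
setGeneric("bodyHeight", function(x) standardGeneric("bodyHeight"))

#' @rdname phantom-accessors
#' @export
setGeneric("imagedRange", function(x) standardGeneric("imagedRange"))

#' @rdname phantom-accessors
#' @export
setGeneric("bodyMask", function(x) standardGeneric("bodyMask"))

#' @rdname phantom-accessors
#' @param code integer structure code.
#' @aliases structureMask
#' @export
setGeneric("structureMask", function(x, code) standardGeneric("structureMask"))
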