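#' Accessor generics
#'
#' Small accessor layer over the S4 containers: `geometry()` returns the
#' [VoxelGeometry-class] of a volume or mask, `volData()` the raw 3-D
#' array, `voxelVolume()` the voxel volume in mm^3, `nSlices()` the slice
#' count, and `selectRoi()` crops an object to an L4/L5-anchored ROI.
#'
#' @param x An object.
#' @param roi A [RoiSpec-class].
#' @return `geometry()`: a [VoxelGeometry-class]; `volData()`: an array;
#'   `voxelVolume()`, `nSlices()`: a number; `selectRoi()`: an object of
#'   the same class cropped to `2 * halfWidth + 1` slices.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname selectRoi
#' @export
setGeneric("selectRoi", function(x, roi) standardGeneric("selectRoi"))
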