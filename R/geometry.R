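#' Construct a voxel geometry
#'
#' @param dx,dy In-plane voxel size in mm.
#' @param dz Slice thickness in mm.
#' @param nSlices Number of transverse slices.
#' @return A [VoxelGeometry-class].
#' @examples
#' g <- voxelGeometry(1.25, 1.25, 3, 150)
#' voxelVolume(g)  # 4.6875 mm^3
#' @export
voxelGeometry <- function(dx = 1.25, dy = 1.25, dz = 3, nSlices = 150L) {
  new("VoxelGeometry", dx = as.numeric(dx), dy = as.numeric(dy),
      dz = as.numeric(dz), nSlices = as.integer(nSlices))
}

#' Construct an image volume
#'
#' @param data 3-D numeric array indexed `[x, y, slice]`.
#' @param geometry A [VoxelGeometry-class]; defaults to unit in-plane
#'   voxels if missing.
#' @param label Volume label, one of `"in_phase"`, `"opposed_phase"`,
#'   `"fat_only"`, `"water_only"`, `"other"`.
#' @return An [ImageVolume-class].
#' @export
imageVolume <- function(data, geometry = NULL, label = "other") {
  data <- as.array(data)
  storage.mode(data) <- "double"
  if (is.null(geometry))
    geometry <- voxelGeometry(1, 1, 1, dim(data)[3])
  new("ImageVolume", data = data, geometry = geometry, label = label)
}

#' Construct a binary mask
#'
#' @param data 3-D array of 0/1 (or logical) values.
#' @param geometry A [VoxelGeometry-class]; defaults to unit voxels.
#' @param region Region label, one of `"body"`, `"fat"`, `"SAT"`, `"VAT"`,
#'   `"TAT"`, `"cavity"`, `"custom"`.
#' @return A [Mask-class].
#' @export
maskVolume <- function(data, geometry = NULL, region = "custom") {
  data <- as.array(data)
  storage.mode(data) <- "integer"
  if (is.null(geometry))
    geometry <- voxelGeometry(1, 1, 1, dim(data)[3])
  new("Mask", data = data, geometry = geometry, region = region)
}

#' @rdname accessors
setMethod("geometry", "ImageVolume", function(x) x@geometry)
#' @rdname accessors
setMethod("geometry", "Mask", function(x) x@geometry)

#' @rdname accessors
setMethod("volData", "ImageVolume", function(x) x@data)
#' @rdname accessors
setMethod("volData", "Mask", function(x) x@data)

#' @rdname accessors
setMethod("voxelVolume", "VoxelGeometry", function(x) x@dx * x@dy * x@dz)
#' @rdname accessors
setMethod("voxelVolume", "ImageVolume", function(x) voxelVolume(x@geometry))
#' @rdname accessors
setMethod("voxelVolume", "Mask", function(x) voxelVolume(x@geometry))

#' @rdname accessors
setMethod("nSlices", "VoxelGeometry", function(x) x@nSlices)
#' @rdname accessors
setMethod("nSlices", "ImageVolume", function(x) x@geometry@nSlices)
#' @rdname accessors
setMethod("nSlices", "Mask", function(x) x@geometry@nSlices)

## shared helper: same-shape check
.checkSameGeometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a@data), dim(b@data)))
    stop(sprintf("shape mismatch between %s: %s vs %s", what,
                 paste(dim(a@data), collapse = "x"),
                 paste(dim(b@data), collapse = "x")))
  ga <- a@geometry; gb <- b@geometry
  if (abs(ga@dx - gb@dx) > 1e-9 || abs(ga@dy - gb@dy) > 1e-9 ||
      abs(ga@dz - gb@dz) > 1e-9)
    stop(sprintf("voxel size mismatch between %s", what))
  invisible(TRUE)
}
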