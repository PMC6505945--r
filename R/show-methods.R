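#' @describeIn voxelGeometry Display method.
#' @param object Object to display.
#' @export
setMethod("show", "VoxelGeometry", function(object) {
  cat(sprintf("VoxelGeometry: %g x %g x %g mm (%d slices), voxel %g mm^3\n",
              object@dx, object@dy, object@dz, object@nSlices,
              voxelVolume(object)))
})

#' @describeIn imageVolume Display method.
#' @param object Object to display.
#' @export
setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume <%s>: %d x %d x %d, voxels %g x %g x %g mm, range [%.4g, %.4g]\n",
              object@label, d[1], d[2], d[3], object@geometry@dx,
              object@geometry@dy, object@geometry@dz,
              min(object@data), max(object@data)))
})

#' @describeIn maskVolume Display method.
#' @param object Object to display.
#' @export
setMethod("show", "Mask", function(object) {
  d <- dim(object@data)
  cat(sprintf("Mask <%s>: %d x %d x %d, %d foreground voxels (%.2f mL)\n",
              object@region, d[1], d[2], d[3], sum(object@data),
              sum(object@data) * voxelVolume(object) / 1000))
})

#' @describeIn fatVolumes Display method.
#' @param object Object to display.
#' @export
setMethod("show", "FatVolumes", function(object) {
  cat(sprintf(
    "FatVolumes: VAT %.1f, SAT %.1f, TAT %.1f, abdominal %.1f mL; VAT/SAT %.2f, VAT/TAT %.2f\n",
    object@vatMl, object@satMl, object@tatMl, object@abdominalMl,
    object@vatSatRatio, object@vatTatRatio))
})

#' @describeIn splitSatVat Display method for segmentation results.
#' @param object Object to display.
#' @export
setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult\n")
  cat(sprintf("  ROI: L4/L5 slice %d, half-width %d (%d slices), central %d\n",
              object@roi@l4l5Index, object@roi@halfWidth,
              2L * object@roi@halfWidth + 1L, object@roi@centralCount))
  for (s in c("body", "fat", "sat", "vat"))
    cat(sprintf("  %-5s %d voxels\n", s, sum(slot(object, s)@data)))
})

#' @describeIn blandAltman Display method.
#' @param object Object to display.
#' @export
setMethod("show", "BlandAltman", function(object) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.4g [95%% CI %.4g to %.4g], LoA %.4g to %.4g\n",
    object@n, object@bias, object@ci[1], object@ci[2], object@loa[1],
    object@loa[2]))
})

#' @describeIn compareSegmentations Display method for validation reports.
#' @param object Object to display.
#' @export
setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport\n  Dice:",
      paste(sprintf("%s %.4f", names(object@dice), object@dice),
            collapse = ", "), "\n")
  if (length(object@blandAltman)) {
    for (rg in names(object@blandAltman)) {
      ba <- object@blandAltman[[rg]]
      cat(sprintf("  %-9s bias %.4g [CI %.4g, %.4g]\n", rg, ba@bias,
                  ba@ci[1], ba@ci[2]))
    }
  }
})

#' @describeIn phantomSpec Display method.
#' @param object Object to display.
#' @export
setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: body %g x %g mm, SAT ring %.1f mm, %d VAT blob(s), %s, noise SD %g\n",
    object@bodySemiAxes[1], object@bodySemiAxes[2], object@satThickness,
    length(object@vatBlobs),
    if (is.null(object@marrow)) "no marrow" else "marrow", object@noiseSd))
})

#' @describeIn generatePhantom Display method for ground truth.
#' @param object Object to display.
#' @export
setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth (central slab)\n  voxelised: ")
  show(object@volumes)
  cat("  analytic:  ")
  show(object@analytic)
})
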