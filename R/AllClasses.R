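#' @import methods
NULL

## Central S4 data model: voxel grids (image volumes and binary masks) with
## explicit voxel geometry, plus the small value classes carried through the
## segmentation and validation stages.  Slice axis is always the third array
## dimension (inferior-superior); user-facing slice indices are 0-based.

.VOLUME_LABELS <- c("in_phase", "opposed_phase", "fat_only", "water_only",
                    "other")
.MASK_REGIONS <- c("body", "fat", "SAT", "VAT", "TAT", "cavity", "custom")

#' Voxel geometry of a 3-D acquisition
#'
#' Stores the reconstructed voxel size in millimetres and the number of
#' transverse slices.  The voxel volume `dx * dy * dz` (mm^3) converts mask
#' voxel counts into physical volumes.
#'
#' @slot dx,dy numeric(1). In-plane voxel size in mm.
#' @slot dz numeric(1). Slice thickness in mm.
#' @slot nSlices integer(1). Number of transverse slices.
#' @exportClass VoxelGeometry
setClass("VoxelGeometry",
  representation(dx = "numeric", dy = "numeric", dz = "numeric",
                 nSlices = "integer"),
  prototype(dx = 1.25, dy = 1.25, dz = 3, nSlices = 150L))

setValidity("VoxelGeometry", function(object) {
  msg <- character()
  for (s in c("dx", "dy", "dz")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  if (length(object@nSlices) != 1 || is.na(object@nSlices) ||
      object@nSlices < 1L)
    msg <- c(msg, "nSlices must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' A 3-D scalar image volume
#'
#' Carrier for in-phase, opposed-phase, fat-only and water-only images.
#' Data are indexed `[x, y, slice]` with the third axis inferior-superior.
#' Opposed-phase volumes are phase-corrected and signed, so intensities may
#' be negative; all values must be finite.
#'
#' @slot data 3-D numeric array.
#' @slot geometry A [VoxelGeometry-class].
#' @slot label character(1), one of `"in_phase"`, `"opposed_phase"`,
#'   `"fat_only"`, `"water_only"`, `"other"`.
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(data = "array", geometry = "VoxelGeometry",
                 label = "character"))

setValidity("ImageVolume", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3)
    msg <- c(msg, "data must be a 3-D array")
  else if (d[3] != object@geometry@nSlices)
    msg <- c(msg, sprintf("third dimension (%d) must equal geometry nSlices (%d)",
                          d[3], object@geometry@nSlices))
  if (!all(is.finite(object@data)))
    msg <- c(msg, "intensities must be finite")
  if (length(object@label) != 1 || !object@label %in% .VOLUME_LABELS)
    msg <- c(msg, paste("label must be one of:",
                        paste(.VOLUME_LABELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' A binary 3-D mask aligned to an image volume
#'
#' @slot data 3-D integer array with values in `{0, 1}`.
#' @slot geometry A [VoxelGeometry-class].
#' @slot region character(1), one of `"body"`, `"fat"`, `"SAT"`, `"VAT"`,
#'   `"TAT"`, `"cavity"`, `"custom"`.
#' @exportClass Mask
setClass("Mask",
  representation(data = "array", geometry = "VoxelGeometry",
                 region = "character"))

setValidity("Mask", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3)
    msg <- c(msg, "data must be a 3-D array")
  else if (d[3] != object@geometry@nSlices)
    msg <- c(msg, sprintf("third dimension (%d) must equal geometry nSlices (%d)",
                          d[3], object@geometry@nSlices))
  if (!all(object@data %in% c(0L, 1L)))
    msg <- c(msg, "mask values must all be 0 or 1")
  if (length(object@region) != 1 || !object@region %in% .MASK_REGIONS)
    msg <- c(msg, paste("region must be one of:",
                        paste(.MASK_REGIONS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' L4/L5-anchored region-of-interest specification
#'
#' The operator marks the slice containing the L4/L5 intervertebral disc;
#' `halfWidth` slices are taken above and below it (51 slices at the
#' default of 25), and final volumes are computed from the central
#' `centralCount` slices only (default 30).
#'
#' @slot l4l5Index integer(1). 0-based slice index of the L4/L5 disc.
#' @slot halfWidth integer(1). Slices selected on each side of the disc.
#' @slot centralCount integer(1). Slices used for final volumetry.
#' @exportClass RoiSpec
setClass("RoiSpec",
  representation(l4l5Index = "integer", halfWidth = "integer",
                 centralCount = "integer"),
  prototype(halfWidth = 25L, centralCount = 30L))

setValidity("RoiSpec", function(object) {
  msg <- character()
  if (object@l4l5Index < 0L) msg <- c(msg, "l4l5Index must be >= 0")
  if (object@halfWidth < 0L) msg <- c(msg, "halfWidth must be >= 0")
  if (object@centralCount < 1L ||
      object@centralCount > 2L * object@halfWidth + 1L)
    msg <- c(msg, sprintf(
      "centralCount (%d) must be in [1, 2*halfWidth + 1 = %d]",
      object@centralCount, 2L * object@halfWidth + 1L))
  if (length(msg)) msg else TRUE
})

#' Fat-image thresholding specification
#'
#' @slot method character(1), `"otsu"` or `"fixed"`.
#' @slot value numeric(1). Required intensity threshold when `method` is
#'   `"fixed"`; ignored otherwise.
#' @slot perSlice logical(1). Compute the Otsu threshold per slice rather
#'   than once over the whole volume.
#' @exportClass ThresholdSpec
setClass("ThresholdSpec",
  representation(method = "character", value = "numeric",
                 perSlice = "logical"),
  prototype(method = "otsu", value = NA_real_, perSlice = FALSE))

setValidity("ThresholdSpec", function(object) {
  msg <- character()
  if (!object@method %in% c("otsu", "fixed"))
    msg <- c(msg, "method must be 'otsu' or 'fixed'")
  if (object@method == "fixed" &&
      (!is.finite(object@value) || object@value < 0))
    msg <- c(msg, "a fixed threshold requires a finite value >= 0")
  if (length(msg)) msg else TRUE
})

#' Morphological parameters of the segmentation
#'
#' All radii are in voxels and all processing is 2-D per transverse slice.
#' `shellDepth` defines the body-boundary shell used to seed the
#' subcutaneous compartment: fat components touching the shell are SAT,
#' fat inside the largest remaining interior component (the abdominal
#' cavity) is VAT.
#'
#' @slot bodyCloseRadius integer(1). Closing radius for the body mask.
#' @slot bodyFillHoles logical(1). Fill interior holes of the body mask.
#' @slot shellDepth integer(1). Depth (voxels) of the body-boundary shell.
#' @slot fatOpenRadius integer(1). Opening radius applied to the fat mask.
#' @slot connectivity integer(1). 2-D pixel neighbourhood, 4 or 8.
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(bodyCloseRadius = "integer", bodyFillHoles = "logical",
                 shellDepth = "integer", fatOpenRadius = "integer",
                 connectivity = "integer"),
  prototype(bodyCloseRadius = 3L, bodyFillHoles = TRUE, shellDepth = 2L,
            fatOpenRadius = 1L, connectivity = 8L))

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (object@bodyCloseRadius < 0L) msg <- c(msg, "bodyCloseRadius must be >= 0")
  if (object@shellDepth < 0L) msg <- c(msg, "shellDepth must be >= 0")
  if (object@fatOpenRadius < 0L) msg <- c(msg, "fatOpenRadius must be >= 0")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (length(msg)) msg else TRUE
})

#' Result of the SAT/VAT separation
#'
#' Holds the body, total-fat (TAT support), SAT, VAT and abdominal-cavity
#' masks over the selected ROI, together with the ROI and parameters that
#' produced them.  Invariants (checked on construction):
#' `SAT and VAT disjoint`, `SAT + VAT` within the fat mask, fat within the
#' body, cavity within the body.
#'
#' @slot body,fat,sat,vat,cavity [Mask-class] objects sharing one geometry.
#' @slot roi A [RoiSpec-class].
#' @slot params A [SegmentationParams-class].
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(body = "Mask", fat = "Mask", sat = "Mask", vat = "Mask",
                 cavity = "Mask", roi = "RoiSpec",
                 params = "SegmentationParams"))

setValidity("SegmentationResult", function(object) {
  msg <- character()
  dims <- dim(object@body@data)
  for (s in c("fat", "sat", "vat", "cavity"))
    if (!identical(dim(slot(object, s)@data), dims))
      msg <- c(msg, sprintf("%s mask shape differs from body mask", s))
  if (length(msg)) return(msg)
  b <- object@body@data; f <- object@fat@data
  s <- object@sat@data; v <- object@vat@data; cav <- object@cavity@data
  if (any(s + v > 1L)) msg <- c(msg, "SAT and VAT overlap")
  if (any((s | v) & !f)) msg <- c(msg, "SAT/VAT voxels outside the fat mask")
  if (any(f & !b)) msg <- c(msg, "fat voxels outside the body mask")
  if (any(cav & !b)) msg <- c(msg, "cavity voxels outside the body mask")
  if (length(msg)) msg else TRUE
})

#' Per-subject adipose tissue volumes
#'
#' Volumes in mL over the central slab, plus the VAT/SAT and VAT/TAT
#' ratios (0/0 taken as 0).  Invariants: `vat + sat <= tat <= abdominal`.
#'
#' @slot vatMl,satMl,tatMl,abdominalMl numeric(1). Volumes in mL.
#' @slot vatSatRatio,vatTatRatio numeric(1). Dimensionless ratios.
#' @exportClass FatVolumes
setClass("FatVolumes",
  representation(vatMl = "numeric", satMl = "numeric", tatMl = "numeric",
                 abdominalMl = "numeric", vatSatRatio = "numeric",
                 vatTatRatio = "numeric"))

setValidity("FatVolumes", function(object) {
  msg <- character()
  v <- c(object@vatMl, object@satMl, object@tatMl, object@abdominalMl)
  if (length(v) != 4 || !all(is.finite(v)))
    msg <- c(msg, "all four volumes must be single finite numbers")
  else {
    if (any(v < 0)) msg <- c(msg, "volumes must be >= 0")
    tol <- 1e-8 * max(1, v)
    if (object@vatMl + object@satMl > object@tatMl + tol)
      msg <- c(msg, "VAT + SAT must not exceed TAT")
    if (object@tatMl > object@abdominalMl + tol)
      msg <- c(msg, "TAT must not exceed the abdominal volume")
  }
  if (length(msg)) msg else TRUE
})

#' Parametric description of the synthetic abdominal phantom
#'
#' An elliptic-cylinder body with a subcutaneous fat ring of uniform
#' thickness, ellipsoidal visceral fat blobs inside the abdominal cavity,
#' optional non-fat organs, and an optional vertebral body (embedded in the
#' posterior ring) containing a marrow-fat disc.  All linear dimensions are
#' millimetres; blob and organ coordinates are relative to the body axis
#' (x, y) and to the centre of the L4/L5 slice (z).
#'
#' @slot geometry A [VoxelGeometry-class] (default 1.25 x 1.25 x 3 mm,
#'   150 slices).
#' @slot nx,ny integer(1). In-plane matrix size.
#' @slot bodySemiAxes numeric(2). Body ellipse semi-axes (a, b), mm.
#' @slot taper numeric(1). Fractional linear reduction of the semi-axes
#'   from the L4/L5 slice to the volume ends (0 = straight cylinder).
#' @slot satThickness numeric(1). Subcutaneous ring thickness, mm (may be 0).
#' @slot vatBlobs list of `list(center = c(x, y, z), radii = c(rx, ry, rz))`;
#'   a scalar radius denotes a sphere.
#' @slot organs list of `list(center = c(x, y), semiAxes = c(a, b),
#'   signal = <intensity>)` non-fat elliptic cylinders.
#' @slot marrow `NULL`, or `list(semiAxes = c(a, b), marrowRadius = r)` for
#'   a vertebral body centred posteriorly inside the ring.
#' @slot intensities named numeric, `c(fat = ..., water = ...)`.
#' @slot noiseSd numeric(1). Magnitude-noise standard deviation.
#' @slot l4l5Index integer(1). 0-based L4/L5 slice index.
#' @slot clearanceMm numeric(1). Minimum distance (mm) from every blob to
#'   the inner ring boundary, and half the minimum blob-blob gap.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(geometry = "VoxelGeometry", nx = "integer", ny = "integer",
                 bodySemiAxes = "numeric", taper = "numeric",
                 satThickness = "numeric", vatBlobs = "list",
                 organs = "list", marrow = "ANY", intensities = "numeric",
                 noiseSd = "numeric", l4l5Index = "integer",
                 clearanceMm = "numeric"))

#' Analytic ground truth of a phantom
#'
#' @slot body,fat,sat,vat [Mask-class] voxelised truth masks (>= 50%
#'   occupancy rule).
#' @slot volumes A [FatVolumes-class]: voxelised volumes over the central
#'   slab.
#' @slot analytic A [FatVolumes-class]: closed-form volumes over the same
#'   slab.
#' @slot surfaceVoxels named numeric. Count of partial-occupancy (surface)
#'   voxels per region over the central slab; the partial-volume error
#'   bound is this count times the voxel volume.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(body = "Mask", fat = "Mask", sat = "Mask", vat = "Mask",
                 volumes = "FatVolumes", analytic = "FatVolumes",
                 surfaceVoxels = "numeric"))

#' Bland-Altman agreement between two paired measurement series
#'
#' Differences are taken as `x - y` (conventionally reference minus
#' automated).  `loa` are the 95% limits of agreement
#' (bias +/- 1.96 SD of differences); `ci` is the t-based 95% confidence
#' interval of the bias (n - 1 degrees of freedom).  Both are reported
#' because published agreement tables do not always state which of the two
#' their "95% CI" means.
#'
#' @slot bias numeric(1). Mean paired difference.
#' @slot sdDiff numeric(1). SD of the paired differences.
#' @slot loa numeric(2). Limits of agreement, low then high.
#' @slot ci numeric(2). Confidence interval of the bias, low then high.
#' @slot n integer(1). Number of pairs.
#' @exportClass BlandAltman
setClass("BlandAltman",
  representation(bias = "numeric", sdDiff = "numeric", loa = "numeric",
                 ci = "numeric", n = "integer"))

setValidity("BlandAltman", function(object) {
  msg <- character()
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (length(object@loa) != 2 || object@loa[1] > object@loa[2] + 1e-12)
    msg <- c(msg, "loa must be c(low, high)")
  if (length(object@ci) != 2 ||
      object@ci[1] > object@bias + 1e-12 ||
      object@ci[2] < object@bias - 1e-12)
    msg <- c(msg, "ci must bracket the bias")
  if (length(msg)) msg else TRUE
})

#' Validation report: Dice overlap and volume agreement
#'
#' @slot dice named numeric in \[0, 1\]: Dice coefficient per region (at
#'   cohort level, the per-region mean).
#' @slot volumesAuto,volumesRef [FatVolumes-class] (cohort level: means).
#' @slot blandAltman named list of [BlandAltman-class] per region (empty
#'   for a single-subject comparison).
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(dice = "numeric", volumesAuto = "FatVolumes",
                 volumesRef = "FatVolumes", blandAltman = "list"))

setValidity("ValidationReport", function(object) {
  if (length(object@dice) &&
      (any(object@dice < -1e-12) || any(object@dice > 1 + 1e-12)))
    return("Dice coefficients must lie in [0, 1]")
  TRUE
})
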