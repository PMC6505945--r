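#' Construct an ROI specification
#'
#' @param l4l5Index 0-based slice index of the L4/L5 intervertebral disc
#'   (operator input).
#' @param halfWidth Slices taken above and below the disc (51-slice ROI at
#'   the default of 25).
#' @param centralCount Central slices used for the final volumes
#'   (default 30).
#' @return A [RoiSpec-class].
#' @export
roiSpec <- function(l4l5Index, halfWidth = 25L, centralCount = NULL) {
  hw <- as.integer(halfWidth)
  if (is.null(centralCount)) centralCount <- min(30L, 2L * hw + 1L)
  new("RoiSpec", l4l5Index = as.integer(l4l5Index), halfWidth = hw,
      centralCount = as.integer(centralCount))
}

#' Construct a threshold specification
#'
#' @param method `"otsu"` (data-driven, default) or `"fixed"` (operator
#'   supplied, matching the manual threshold setting of the original
#'   protocol).
#' @param value Intensity threshold, required when `method = "fixed"`.
#' @param perSlice Compute the Otsu threshold per slice instead of once
#'   over the whole ROI.
#' @return A [ThresholdSpec-class].
#' @export
thresholdSpec <- function(method = c("otsu", "fixed"), value = NA_real_,
                          perSlice = FALSE) {
  method <- match.arg(method)
  new("ThresholdSpec", method = method, value = as.numeric(value),
      perSlice = isTRUE(perSlice))
}

#' Construct segmentation parameters
#'
#' @param bodyCloseRadius Closing radius (voxels) for the body mask.
#' @param bodyFillHoles Fill interior holes of the body mask.
#' @param shellDepth Depth (voxels) of the body-boundary shell that seeds
#'   the subcutaneous compartment.
#' @param fatOpenRadius Opening radius (voxels) applied to the fat mask
#'   before component analysis (suppresses thin leakage channels between
#'   SAT and VAT).
#' @param connectivity 2-D pixel neighbourhood, 4 or 8.
#' @return A [SegmentationParams-class].
#' @export
segmentationParams <- function(bodyCloseRadius = 3L, bodyFillHoles = TRUE,
                               shellDepth = 2L, fatOpenRadius = 1L,
                               connectivity = 8L) {
  new("SegmentationParams", bodyCloseRadius = as.integer(bodyCloseRadius),
      bodyFillHoles = isTRUE(bodyFillHoles),
      shellDepth = as.integer(shellDepth),
      fatOpenRadius = as.integer(fatOpenRadius),
      connectivity = as.integer(connectivity))
}

## 0-based half-open slice window of the ROI
.roiWindow <- function(roi, nTotal) {
  lo <- roi@l4l5Index - roi@halfWidth
  hi <- roi@l4l5Index + roi@halfWidth + 1L
  if (lo < 0L)
    stop(sprintf(
      "ROI needs %d more slice(s) below the L4/L5 index %d (half-width %d)",
      -lo, roi@l4l5Index, roi@halfWidth))
  if (hi > nTotal)
    stop(sprintf(
      "ROI needs %d more slice(s) above the L4/L5 index %d (half-width %d, volume has %d slices)",
      hi - nTotal, roi@l4l5Index, roi@halfWidth, nTotal))
  c(lo, hi)
}

## 0-based half-open central slab window around centre index `centre`
## (asymmetric ceiling/floor convention: [c - ceil(k/2) + 1, c + floor(k/2) + 1))
.centralWindow <- function(centre, k) {
  c(centre - ceiling(k / 2) + 1L, centre + floor(k / 2) + 1L)
}

.cropSlices <- function(x, lo, hi) {
  ## lo/hi are a 0-based half-open window
  idx <- (lo + 1L):hi
  g <- x@geometry
  g2 <- voxelGeometry(g@dx, g@dy, g@dz, length(idx))
  if (is(x, "Mask"))
    maskVolume(x@data[, , idx, drop = FALSE], g2, x@region)
  else
    imageVolume(x@data[, , idx, drop = FALSE], g2, x@label)
}

#' Crop a volume or mask to the L4/L5-anchored ROI
#'
#' Selects the `2 * halfWidth + 1` slices centred (0-based, half-open
#' `[l4l5 - halfWidth, l4l5 + halfWidth + 1)`) on the operator-marked
#' L4/L5 slice.  Errors name the slice deficit if the volume does not
#' extend far enough on either side.
#'
#' @param x An [ImageVolume-class] or [Mask-class].
#' @param roi A [RoiSpec-class].
#' @return Object of the same class with `2 * halfWidth + 1` slices.
#' @examples
#' v <- imageVolume(array(0, c(4, 4, 150)), voxelGeometry(1.25, 1.25, 3, 150))
#' nSlices(selectRoi(v, roiSpec(75)))  # 51
#' @name selectRoi
NULL

#' @rdname selectRoi
setMethod("selectRoi", "ImageVolume", function(x, roi) {
  w <- .roiWindow(roi, nSlices(x))
  .cropSlices(x, w[1], w[2])
})

#' @rdname selectRoi
setMethod("selectRoi", "Mask", function(x, roi) {
  w <- .roiWindow(roi, nSlices(x))
  .cropSlices(x, w[1], w[2])
})

#' Extract the total body mask
#'
#' Per slice: Otsu threshold on intensity, morphological closing
#' (`bodyCloseRadius`), hole filling, then the largest connected
#' component.  Intended for the ROI-cropped in-phase volume (or the
#' water + fat sum).  A slice on which no body is found raises a
#' segmentation failure naming the slice.
#'
#' @param inPhase An [ImageVolume-class] (ROI-cropped in-phase image).
#' @param params A [SegmentationParams-class].
#' @return A [Mask-class] with region `"body"`.
#' @export
buildBodyMask <- function(inPhase, params = segmentationParams()) {
  stopifnot(is(inPhase, "ImageVolume"))
  arr <- inPhase@data
  ns <- dim(arr)[3]
  out <- array(0L, dim(arr))
  rng <- range(arr)
  for (k in seq_len(ns)) {
    sl <- arr[, , k]
    thr <- .otsuValue(as.vector(sl))
    if (is.na(thr))
      stop(sprintf("body segmentation failed on slice %d (0-based): constant intensity",
                   k - 1L))
    out[, , k] <- as.integer(sl >= thr)
  }
  out <- .binClose(out, params@bodyCloseRadius)
  if (params@bodyFillHoles)
    out <- fillHolesSlices(out, params@connectivity)
  out <- .largestComponentSlices(out, params@connectivity,
                                 failOnEmpty = TRUE, what = "body mask")
  if (params@bodyFillHoles)  # closing after component selection can reopen rims
    out <- fillHolesSlices(out, params@connectivity)
  maskVolume(out, inPhase@geometry, "body")
}

#' Threshold the fat image inside the body mask
#'
#' `fat_mask = (fat >= threshold) & body`, followed by a morphological
#' opening of `fatOpenRadius`.  With `method = "otsu"` the threshold is
#' computed from the in-body fat intensities (whole volume, or per slice
#' when `perSlice`).  A fixed threshold below the in-body background mode
#' logs a warning; an empty result warns and returns the empty mask.
#'
#' @param fat An [ImageVolume-class] (fat-only image, ROI-cropped).
#' @param body A [Mask-class] from [buildBodyMask()].
#' @param thr A [ThresholdSpec-class].
#' @param params A [SegmentationParams-class].
#' @return A [Mask-class] with region `"fat"` and attribute `"threshold"`
#'   (the threshold(s) used).
#' @export
buildFatMask <- function(fat, body, thr = thresholdSpec(),
                         params = segmentationParams()) {
  stopifnot(is(fat, "ImageVolume"), is(body, "Mask"))
  .checkSameGeometry(fat, body, "fat image and body mask")
  arr <- fat@data
  b <- body@data
  inBody <- arr[b == 1L]
  if (!length(inBody)) {
    warning("body mask is empty; returning an empty fat mask")
    return(maskVolume(array(0L, dim(arr)), fat@geometry, "fat"))
  }
  if (thr@method == "fixed") {
    ## background mode: histogram mode of the sub-Otsu (non-fat) in-body
    ## intensities; a fixed threshold below it would flood the background
    t0 <- .otsuValue(inBody)
    bg <- if (is.na(t0)) inBody else inBody[inBody < t0]
    if (!length(bg)) bg <- inBody
    rng <- range(bg)
    if (rng[1] < rng[2]) {
      br <- seq(rng[1], rng[2], length.out = 65L)
      cnt <- tabulate(findInterval(bg, br, rightmost.closed = TRUE,
                                   all.inside = TRUE), nbins = 64L)
      bgMode <- (br[which.max(cnt)] + br[which.max(cnt) + 1L]) / 2
    } else bgMode <- rng[1]
    if (thr@value < bgMode)
      warning(sprintf(
        "fixed fat threshold %.4g is below the in-body background mode %.4g",
        thr@value, bgMode))
    out <- array(as.integer(arr >= thr@value), dim(arr))
    used <- thr@value
  } else if (thr@perSlice) {
    out <- array(0L, dim(arr))
    used <- rep(NA_real_, dim(arr)[3])
    for (k in seq_len(dim(arr)[3])) {
      sl <- arr[, , k]
      vals <- sl[b[, , k] == 1L]
      tk <- if (length(vals)) .otsuValue(vals) else NA_real_
      if (is.na(tk)) next
      used[k] <- tk
      out[, , k] <- as.integer(sl >= tk)
    }
  } else {
    t0 <- .otsuValue(inBody)
    if (is.na(t0)) {
      warning("in-body fat intensities are constant; returning an empty fat mask")
      return(maskVolume(array(0L, dim(arr)), fat@geometry, "fat"))
    }
    out <- array(as.integer(arr >= t0), dim(arr))
    used <- t0
  }
  out <- out * b
  storage.mode(out) <- "integer"
  out <- .binOpen(out, params@fatOpenRadius)
  out <- out * b  # opening dilates back; stay inside the body
  storage.mode(out) <- "integer"
  if (sum(out) == 0L)
    warning("fat mask is empty inside the body")
  m <- maskVolume(out, fat@geometry, "fat")
  attr(m, "threshold") <- used
  m
}

#' Separate subcutaneous from visceral fat by positional priors
#'
#' Training-free separation applied per slice: (1) the body-boundary
#' shell is the body minus its erosion by `shellDepth`; (2) SAT is the
#' union of fat components (at the configured connectivity) that touch
#' the shell; (3) the abdominal cavity is the largest connected component
#' of `body \ (SAT | shell)`, hole-filled; (4) VAT is the fat inside the
#' cavity and not in SAT.  Fat in neither compartment (vertebral marrow,
#' intermuscular fat) stays in the total-fat mask only, so TAT can exceed
#' SAT + VAT.  The partition invariants are asserted on every run.
#'
#' @param fatMask A [Mask-class] from [buildFatMask()].
#' @param body A [Mask-class] from [buildBodyMask()].
#' @param params A [SegmentationParams-class].
#' @param roi A [RoiSpec-class] recorded in the result (defaults to a
#'   window centred on the middle slice of `fatMask`).
#' @return A [SegmentationResult-class].
#' @export
splitSatVat <- function(fatMask, body, params = segmentationParams(),
                        roi = NULL) {
  stopifnot(is(fatMask, "Mask"), is(body, "Mask"))
  .checkSameGeometry(fatMask, body, "fat mask and body mask")
  f <- fatMask@data
  b <- body@data
  if (any(f & !b))
    stop("fat mask must lie inside the body mask")
  ns <- dim(f)[3]
  if (is.null(roi)) {
    hw <- (ns - 1L) %/% 2L
    roi <- roiSpec(hw, hw, min(30L, ns))
  }
  conn <- params@connectivity
  sat <- array(0L, dim(f))
  vat <- array(0L, dim(f))
  cav <- array(0L, dim(f))
  noSatSlices <- integer()
  noCavSlices <- integer()
  for (k in seq_len(ns)) {
    bk <- b[, , k]
    fk <- f[, , k]
    if (params@shellDepth >= 1L) {
      ek <- EBImage::erode(bk, .discBrush(params@shellDepth))
      storage.mode(ek) <- "integer"
      shell <- bk - ek
    } else {
      shell <- bk * 0L
    }
    lab <- .labelComponents2D(matrix(as.integer(fk), nrow(fk)), conn)
    satLabels <- setdiff(unique(lab[shell == 1L & lab > 0L]), 0L)
    sk <- matrix(0L, nrow(fk), ncol(fk))
    if (length(satLabels)) {
      sk <- matrix(as.integer(lab %in% satLabels), nrow(fk))
    } else if (sum(fk) > 0L) {
      noSatSlices <- c(noSatSlices, k - 1L)
    }
    interior <- as.integer(bk == 1L & sk == 0L & shell == 0L)
    ilab <- .labelComponents2D(matrix(interior, nrow(fk)), conn)
    ck <- matrix(0L, nrow(fk), ncol(fk))
    if (max(ilab) > 0L) {
      counts <- tabulate(ilab[ilab > 0L])
      ck <- matrix(as.integer(ilab == which.max(counts)), nrow(fk))
      ck <- .fillHoles2D(ck, conn)
    } else if (sum(fk) > 0L) {
      noCavSlices <- c(noCavSlices, k - 1L)
    }
    vk <- as.integer(fk == 1L & ck == 1L & sk == 0L)
    sat[, , k] <- sk
    vat[, , k] <- vk
    cav[, , k] <- ck
  }
  if (sum(f) > 0L && sum(sat) == 0L)
    warning("no fat component touches the body-boundary shell; SAT is empty")
  if (sum(cav) == 0L)
    warning("abdominal cavity is empty; VAT is empty")
  g <- fatMask@geometry
  res <- new("SegmentationResult",
             body = body,
             fat = maskVolume(f, g, "fat"),
             sat = maskVolume(sat, g, "SAT"),
             vat = maskVolume(vat, g, "VAT"),
             cavity = maskVolume(cav, g, "cavity"),
             roi = roi, params = params)
  validObject(res)  # partition invariants
  res
}

#' Compute central-slab adipose tissue volumes
#'
#' Restricts every mask to the `centralCount` central slices of the ROI
#' (half-open 0-based window `[c - ceil(k/2) + 1, c + floor(k/2) + 1)`
#' around the L4/L5 slice, which sits at index `halfWidth` within the
#' ROI) and converts voxel counts to mL with the voxel volume.  TAT is
#' measured on the fat mask and the abdominal volume on the body mask.
#'
#' @param result A [SegmentationResult-class].
#' @param centralCount Override for the slab depth (defaults to the ROI's
#'   `centralCount`).
#' @return A [FatVolumes-class].
#' @examples
#' ## 1000 voxels at 1.25 x 1.25 x 3 mm^3 = 4.6875 mL
#' @export
computeVolumes <- function(result, centralCount = NULL) {
  stopifnot(is(result, "SegmentationResult"))
  roi <- result@roi
  k <- if (is.null(centralCount)) roi@centralCount else
    as.integer(centralCount)
  ns <- nSlices(result@body)
  if (k > ns)
    stop(sprintf("central slab of %d slices exceeds the ROI depth %d", k, ns))
  w <- .centralWindow(roi@halfWidth, k)
  if (w[1] < 0L || w[2] > ns)
    stop(sprintf("central slab [%d, %d) lies outside the ROI of %d slices",
                 w[1], w[2], ns))
  idx <- (w[1] + 1L):w[2]
  vv <- voxelVolume(result@body) / 1000  # mL per voxel
  cnt <- function(m) sum(m@data[, , idx])
  fatVolumes(vatMl = cnt(result@vat) * vv,
             satMl = cnt(result@sat) * vv,
             tatMl = cnt(result@fat) * vv,
             abdominalMl = cnt(result@body) * vv)
}

#' Run the full segmentation pipeline
#'
#' Convenience wrapper: crops the fat-only and in-phase images to the
#' L4/L5-anchored ROI, extracts the body mask from the in-phase image,
#' thresholds the fat image, separates SAT from VAT, and computes the
#' central-slab volumes.
#'
#' @param fat Fat-only [ImageVolume-class] (full volume).
#' @param inPhase In-phase [ImageVolume-class] used for the body mask; if
#'   `NULL`, the fat image is used (only sensible when non-fat tissue has
#'   appreciable fat-image signal).
#' @param roi A [RoiSpec-class].
#' @param thr A [ThresholdSpec-class].
#' @param params A [SegmentationParams-class].
#' @return List with elements `result` ([SegmentationResult-class]) and
#'   `volumes` ([FatVolumes-class]).
#' @export
segmentAbdomen <- function(fat, inPhase = NULL, roi,
                           thr = thresholdSpec(),
                           params = segmentationParams()) {
  stopifnot(is(fat, "ImageVolume"))
  fatRoi <- selectRoi(fat, roi)
  anatomy <- if (is.null(inPhase)) fatRoi else selectRoi(inPhase, roi)
  body <- buildBodyMask(anatomy, params)
  fatMask <- buildFatMask(fatRoi, body, thr, params)
  result <- splitSatVat(fatMask, body, params, roi = roi)
  list(result = result, volumes = computeVolumes(result))
}
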