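#' Dice overlap coefficient between two masks
#'
#' `2 |A & B| / (|A| + |B|)`.  Two empty masks agree by convention
#' (Dice 1, logged).
#'
#' @param a,b [Mask-class] objects of identical geometry.
#' @return A number in \[0, 1\].
#' @examples
#' g <- voxelGeometry(1, 1, 1, 1)
#' a <- maskVolume(array(c(1, 1, 1, 1, 0, 0), c(6, 1, 1)), g)
#' b <- maskVolume(array(c(0, 1, 1, 1, 1, 1), c(6, 1, 1)), g)
#' diceCoefficient(a, b)  # 2 * 3 / (4 + 6) = 0.6
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(is(a, "Mask"), is(b, "Mask"))
  .checkSameGeometry(a, b, "masks")
  na <- sum(a@data)
  nb <- sum(b@data)
  if (na + nb == 0) {
    .logMsg("both masks empty: Dice = 1 by convention")
    return(1)
  }
  2 * sum(a@data * b@data) / (na + nb)
}

#' Bland-Altman agreement analysis
#'
#' Paired differences `d = x - y` (conventionally reference minus
#' automated).  Reports the bias (mean difference), the SD of
#' differences, the 95% limits of agreement `bias +/- 1.96 sd`, and the
#' t-based 95% confidence interval of the bias with `n - 1` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @param conf Confidence level for the CI of the bias.
#' @return A [BlandAltman-class].
#' @examples
#' ba <- blandAltman(c(10, 12, 9, 11), c(10.5, 11, 9.5, 11.5))
#' ba@bias
#' @export
blandAltman <- function(x, y, conf = 0.95) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  n <- length(x)
  if (n < 2)
    stop("Bland-Altman analysis needs at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  sdDiff <- stats::sd(d)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * sdDiff / sqrt(n)
  new("BlandAltman", bias = bias, sdDiff = sdDiff,
      loa = c(bias - 1.96 * sdDiff, bias + 1.96 * sdDiff),
      ci = c(bias - half, bias + half), n = as.integer(n))
}

## per-region masks of a SegmentationResult, names as used in reports
.autoRegionMasks <- function(result) {
  list(sat = result@sat, vat = result@vat, tat = result@fat,
       body = result@body)
}

## crop a reference mask to the auto ROI when it covers the full volume
.alignRef <- function(ref, auto, roi) {
  if (nSlices(ref) == nSlices(auto)) return(ref)
  selectRoi(ref, roi)
}

#' Compare an automatic segmentation against reference masks
#'
#' Computes the Dice coefficient per region over the central slab of the
#' ROI (the slab used for volumetry), together with the central-slab
#' volumes of both segmentations.  Reference masks spanning the full
#' original volume are cropped to the ROI automatically.  Missing
#' reference regions yield a partial report with a warning.
#'
#' @param auto A [SegmentationResult-class].
#' @param ref Named list of reference [Mask-class] objects; recognised
#'   names are `"sat"`, `"vat"`, `"tat"` (total fat support) and
#'   `"body"`.
#' @param centralOnly Restrict the comparison to the central slab
#'   (default), as in the validation protocol; otherwise the whole ROI.
#' @return A [ValidationReport-class] (single-subject: `blandAltman` is
#'   empty).
#' @export
compareSegmentations <- function(auto, ref, centralOnly = TRUE) {
  stopifnot(is(auto, "SegmentationResult"), is.list(ref))
  known <- c("sat", "vat", "tat", "body")
  missing <- setdiff(c("sat", "vat", "tat"), names(ref))
  if (length(missing))
    warning(sprintf("reference lacks region(s) %s; partial report",
                    paste(missing, collapse = ", ")))
  ref <- ref[intersect(names(ref), known)]
  autoMasks <- .autoRegionMasks(auto)
  roi <- auto@roi
  ns <- nSlices(auto@body)
  if (centralOnly)
    w <- .centralWindow(roi@halfWidth, roi@centralCount)
  crop <- function(m) {
    if (!centralOnly) return(m)
    .cropSlices(m, w[1], w[2])
  }
  dice <- numeric()
  refMl <- c(sat = NA_real_, vat = NA_real_, tat = NA_real_,
             body = NA_real_)
  vv <- voxelVolume(auto@body) / 1000
  for (rg in names(ref)) {
    refMask <- .alignRef(ref[[rg]], auto@body, roi)
    a <- crop(autoMasks[[rg]])
    r <- crop(refMask)
    dice[rg] <- diceCoefficient(a, r)
    refMl[rg] <- sum(r@data) * vv
  }
  volAuto <- computeVolumes(auto,
                            centralCount = if (centralOnly)
                              roi@centralCount else ns)
  ## fall back to the automatic values for regions absent from the
  ## reference, so the partial report still carries a valid volume record
  if (is.na(refMl["tat"]))
    refMl["tat"] <- if (!is.na(refMl["sat"]) && !is.na(refMl["vat"]))
      refMl[["sat"]] + refMl[["vat"]] else volAuto@tatMl
  if (is.na(refMl["sat"])) refMl["sat"] <- volAuto@satMl
  if (is.na(refMl["vat"])) refMl["vat"] <- volAuto@vatMl
  if (is.na(refMl["body"])) refMl["body"] <- volAuto@abdominalMl
  volRef <- fatVolumes(vatMl = refMl[["vat"]], satMl = refMl[["sat"]],
                       tatMl = max(refMl[["tat"]],
                                   refMl[["sat"]] + refMl[["vat"]]),
                       abdominalMl = max(refMl[["body"]], refMl[["tat"]]))
  new("ValidationReport", dice = dice, volumesAuto = volAuto,
      volumesRef = volRef, blandAltman = list())
}

#' Cohort-level validation: mean Dice and Bland-Altman per region
#'
#' Aggregates per-subject [ValidationReport-class] objects: per-region
#' mean Dice, cohort-mean volumes, and Bland-Altman agreement
#' (reference minus automatic) of the VAT, SAT, TAT and abdominal
#' volumes across subjects.
#'
#' @param reports List of [ValidationReport-class] objects from
#'   [compareSegmentations()].
#' @return A [ValidationReport-class] with `blandAltman` filled per
#'   region.
#' @export
cohortValidation <- function(reports) {
  stopifnot(length(reports) >= 2,
            all(vapply(reports, is, TRUE, class2 = "ValidationReport")))
  regions <- Reduce(intersect, lapply(reports, function(r) names(r@dice)))
  dice <- vapply(regions, function(rg)
    mean(vapply(reports, function(r) r@dice[[rg]], 0)), 0)
  getv <- function(which, slot_) vapply(reports, function(r)
    slot(slot(r, which), slot_), 0)
  ba <- list()
  for (fld in c("vatMl", "satMl", "tatMl", "abdominalMl")) {
    rg <- sub("Ml$", "", fld)
    rg <- c(vat = "vat", sat = "sat", tat = "tat",
            abdominal = "abdominal")[[rg]]
    ba[[rg]] <- blandAltman(getv("volumesRef", fld), getv("volumesAuto", fld))
  }
  mvol <- function(which) fatVolumes(
    mean(getv(which, "vatMl")), mean(getv(which, "satMl")),
    mean(getv(which, "tatMl")), mean(getv(which, "abdominalMl")))
  new("ValidationReport", dice = dice, volumesAuto = mvol("volumesAuto"),
      volumesRef = mvol("volumesRef"), blandAltman = ba)
}
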