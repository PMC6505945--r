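#' Read a 3-D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into an [ImageVolume-class].  The volume
#' is reoriented so that the third array axis runs inferior-superior
#' (RAS convention) whenever the header carries a usable orientation, and
#' the header scale slope/intercept is applied so that thresholds operate
#' on physical intensities.  Slice indices used elsewhere in the package
#' (e.g. the L4/L5 anchor) are 0-based.
#'
#' @param path Path to a NIfTI file containing a 3-D image.
#' @param label Volume label to attach (see [imageVolume()]).
#' @param reorient Reorient to RAS using the header orientation codes.
#' @return An [ImageVolume-class].
#' @seealso [writeVolume()], [writeMask()]
#' @export
readVolume <- function(path, label = "other", reorient = TRUE) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop(sprintf("not a readable NIfTI image: %s (%s)",
                                 path, conditionMessage(e))))
  if (reorient) {
    ## images without qform/sform codes carry no orientation to fix
    hdr0 <- RNifti::niftiHeader(img)
    if (hdr0$qform_code > 0 || hdr0$sform_code > 0)
      try(RNifti::orientation(img) <- "RAS", silent = TRUE)
  }
  hdr <- RNifti::niftiHeader(img)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) != 3)
    stop(sprintf("expected a 3-D image, got %d dimensions", length(d)))
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop(sprintf("non-positive voxel sizes in header: %s",
                 paste(signif(pd, 4), collapse = " x ")))
  dat <- as.array(img)
  attributes(dat) <- list(dim = d)
  slope <- hdr$scl_slope
  inter <- hdr$scl_inter
  if (is.finite(slope) && slope != 0 && (slope != 1 || inter != 0))
    dat <- dat * slope + inter
  imageVolume(dat, voxelGeometry(pd[1], pd[2], pd[3], d[3]), label = label)
}

#' Read a NIfTI mask
#'
#' As [readVolume()], then validates that all values are 0/1.
#'
#' @inheritParams readVolume
#' @param region Region label to attach (see [maskVolume()]).
#' @return A [Mask-class].
#' @export
readMask <- function(path, region = "custom", reorient = TRUE) {
  v <- readVolume(path, reorient = reorient)
  maskVolume(round(v@data), v@geometry, region = region)
}

#' Write an image volume to NIfTI
#'
#' Data are stored as float64 so that integer grids round-trip bit-exactly.
#'
#' @param vol An [ImageVolume-class].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "ImageVolume"))
  validObject(vol)
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- c(vol@geometry@dx, vol@geometry@dy, vol@geometry@dz)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a binary mask to NIfTI
#'
#' The mask is validated (values strictly in `{0, 1}`) before writing;
#' reading it back reproduces data and geometry exactly.
#'
#' @param mask A [Mask-class].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "Mask"))
  validObject(mask)
  img <- RNifti::asNifti(mask@data)
  RNifti::pixdim(img) <- c(mask@geometry@dx, mask@geometry@dy,
                           mask@geometry@dz)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Construct a FatVolumes record
#'
#' Ratios are recomputed from the supplied volumes, with the 0/0
#' convention mapping to 0.
#'
#' @param vatMl,satMl,tatMl,abdominalMl Volumes in mL.
#' @return A [FatVolumes-class].
#' @examples
#' fatVolumes(1020, 2540, 3660, 12000)
#' @export
fatVolumes <- function(vatMl, satMl, tatMl, abdominalMl) {
  rat <- function(num, den) if (num == 0 && den == 0) 0 else num / den
  new("FatVolumes", vatMl = as.numeric(vatMl), satMl = as.numeric(satMl),
      tatMl = as.numeric(tatMl), abdominalMl = as.numeric(abdominalMl),
      vatSatRatio = rat(as.numeric(vatMl), as.numeric(satMl)),
      vatTatRatio = rat(as.numeric(vatMl), as.numeric(tatMl)))
}

#' Tabulate adipose tissue volumes
#'
#' @param x A [FatVolumes-class].
#' @return A one-row `data.frame` with columns `VAT_mL`, `SAT_mL`,
#'   `TAT_mL`, `abdominal_mL`, `VAT_SAT_ratio`, `VAT_TAT_ratio`.
#' @export
volumeTable <- function(x) {
  stopifnot(is(x, "FatVolumes"))
  data.frame(VAT_mL = x@vatMl, SAT_mL = x@satMl, TAT_mL = x@tatMl,
             abdominal_mL = x@abdominalMl, VAT_SAT_ratio = x@vatSatRatio,
             VAT_TAT_ratio = x@vatTatRatio)
}

#' Write a one-row CSV volume report
#'
#' Volumes are printed with 1 decimal (mL) and ratios with 2 decimals;
#' ratios are those recomputed from the supplied volumes.
#'
#' @param volumes A [FatVolumes-class].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
writeReport <- function(volumes, path) {
  stopifnot(is(volumes, "FatVolumes"))
  validObject(volumes)
  tab <- volumeTable(volumes)
  out <- data.frame(
    VAT_mL = sprintf("%.1f", tab$VAT_mL),
    SAT_mL = sprintf("%.1f", tab$SAT_mL),
    TAT_mL = sprintf("%.1f", tab$TAT_mL),
    abdominal_mL = sprintf("%.1f", tab$abdominal_mL),
    VAT_SAT_ratio = sprintf("%.2f", tab$VAT_SAT_ratio),
    VAT_TAT_ratio = sprintf("%.2f", tab$VAT_TAT_ratio))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
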