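## Slice-wise binary morphology.  Acquired slices are thick relative to the
## in-plane resolution, so all structural operations are 2-D per transverse
## slice: EBImage supplies the grey/binary filters (disc structuring
## elements), while connected components and hole filling use the compiled
## flood-fill kernels in src/, which expose the 4/8-connectivity choice the
## segmentation contract requires.

.discBrush <- function(radius) {
  if (radius < 1L) return(NULL)
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

.sliceApply <- function(arr, fun) {
  out <- arr
  for (k in seq_len(dim(arr)[3])) out[, , k] <- fun(arr[, , k])
  out
}

#' Connected-component labelling per slice
#'
#' Labels the foreground of every transverse slice independently with the
#' given 2-D pixel connectivity.  Labels restart from 1 on each slice.
#'
#' @param mask 3-D array (0/1 or logical) or [Mask-class].
#' @param connectivity 4 or 8.
#' @return Integer array of per-slice labels (0 = background).
#' @export
labelSlices <- function(mask, connectivity = 8L) {
  arr <- if (is(mask, "Mask")) mask@data else mask
  storage.mode(arr) <- "integer"
  .sliceApply(arr, function(m) .labelComponents2D(m, as.integer(connectivity)))
}

#' Fill interior holes per slice
#'
#' Background components not connected to the slice border become
#' foreground.  The background is traversed with the connectivity dual to
#' the foreground one (8 -> 4, 4 -> 8).
#'
#' @inheritParams labelSlices
#' @return Integer 0/1 array of the same shape.
#' @export
fillHolesSlices <- function(mask, connectivity = 8L) {
  arr <- if (is(mask, "Mask")) mask@data else mask
  storage.mode(arr) <- "integer"
  .sliceApply(arr, function(m) .fillHoles2D(m, as.integer(connectivity)))
}

## keep the largest foreground component on each slice; empty slices stay
## empty unless failOnEmpty names them
.largestComponentSlices <- function(arr, connectivity = 8L,
                                    failOnEmpty = FALSE, what = "mask") {
  storage.mode(arr) <- "integer"
  out <- arr
  for (k in seq_len(dim(arr)[3])) {
    lab <- .labelComponents2D(arr[, , k], as.integer(connectivity))
    if (max(lab) == 0L) {
      if (failOnEmpty)
        stop(sprintf("%s is empty on slice %d (0-based)", what, k - 1L))
      out[, , k] <- 0L
      next
    }
    counts <- tabulate(lab[lab > 0L])
    out[, , k] <- as.integer(lab == which.max(counts))
  }
  out
}

## EBImage round-trip helpers returning integer 0/1 arrays
.binClose <- function(arr, radius) {
  if (radius < 1L) return(arr)
  out <- EBImage::closing(arr, .discBrush(radius))
  storage.mode(out) <- "integer"
  out
}

.binOpen <- function(arr, radius) {
  if (radius < 1L) return(arr)
  out <- EBImage::opening(arr, .discBrush(radius))
  storage.mode(out) <- "integer"
  out
}

.binErode <- function(arr, radius) {
  if (radius < 1L) return(arr)
  out <- EBImage::erode(arr, .discBrush(radius))
  storage.mode(out) <- "integer"
  out
}

## Otsu threshold of an intensity vector (histogram with `levels` bins over
## the value range), via EBImage's between-class-variance maximiser.
.otsuValue <- function(values, levels = 256L) {
  rng <- range(values)
  if (!is.finite(rng[1]) || rng[1] == rng[2])
    return(NA_real_)
  EBImage::otsu(matrix(values, ncol = 1L), range = rng, levels = levels)
}
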