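#' Read segmentation configuration from JSON
#'
#' Accepts a JSON object with optional members `params` (fields of
#' [segmentationParams()]), `threshold` (fields of [thresholdSpec()]) and
#' `roi` (fields of [roiSpec()]); absent fields keep their defaults.
#'
#' @param path Path to a JSON file.
#' @return List with elements `params`, `threshold` and `roi` (the last
#'   `NULL` unless the file carries an `l4l5Index`).
#' @export
readSegmentationConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  fill <- function(fun, given) {
    frm <- formals(fun)
    args <- given[intersect(names(given), names(frm))]
    do.call(fun, args)
  }
  params <- fill(segmentationParams, as.list(cfg$params))
  threshold <- fill(thresholdSpec, as.list(cfg$threshold))
  roi <- NULL
  if (!is.null(cfg$roi$l4l5Index))
    roi <- fill(roiSpec, as.list(cfg$roi))
  list(params = params, threshold = threshold, roi = roi)
}
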