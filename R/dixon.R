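#' Pair of in-phase and opposed-phase Dixon echoes
#'
#' Bundles the two echoes of a 2-point Dixon acquisition after checking
#' that they share one geometry and satisfy the magnitude identity
#' `IP >= |OP|` up to noise.  The tolerance `tau` defaults to 3x the
#' background noise SD, estimated from an 8x8x(all-slice) corner patch of
#' the in-phase magnitude (Rayleigh background, `sd = mean / sqrt(pi/2)`).
#' Voxels exceeding the tolerance are counted; more than `maxViolate`
#' (default 5%) of voxels in violation is treated as a sign/phase error.
#'
#' Scanner opposed-phase output is assumed phase-corrected and signed.
#' Magnitude-only opposed-phase data can be accepted with
#' `magnitudeOP = TRUE`: the sign is then resolved by assuming
#' water-dominant tissue (fat fraction <= 0.5) everywhere, which mirrors
#' fat-dominant voxels below 0.5 and is documented as approximate.
#'
#' @param inPhase,opposedPhase [ImageVolume-class] objects of identical
#'   geometry.
#' @param tau Noise tolerance for the `IP >= |OP|` check; `NULL` for the
#'   3-sigma default.
#' @param magnitudeOP Treat `opposedPhase` as magnitude data (see above).
#' @param maxViolate Maximal tolerated fraction of violating voxels.
#' @return A list of class `"DixonPair"` with elements `inPhase`,
#'   `opposedPhase` and `tau`.
#' @examples
#' g <- voxelGeometry(2, 2, 5, 4)
#' ip <- imageVolume(array(200, c(8, 8, 4)), g, "in_phase")
#' op <- imageVolume(array(0, c(8, 8, 4)), g, "opposed_phase")
#' pair <- dixonPair(ip, op)
#' @export
dixonPair <- function(inPhase, opposedPhase, tau = NULL,
                      magnitudeOP = FALSE, maxViolate = 0.05) {
  stopifnot(is(inPhase, "ImageVolume"), is(opposedPhase, "ImageVolume"))
  .checkSameGeometry(inPhase, opposedPhase, "in-phase and opposed-phase")
  ip <- inPhase@data
  op <- opposedPhase@data
  if (magnitudeOP) {
    ## water-dominant prior: W >= F so the signed OP = W - F is taken >= 0
    op <- abs(op)
    .logMsg("magnitude opposed-phase input: assuming water-dominant voxels")
  }
  if (is.null(tau)) {
    nc <- min(8L, dim(ip)[1]); mc <- min(8L, dim(ip)[2])
    corner <- ip[seq_len(nc), seq_len(mc), , drop = FALSE]
    tau <- 3 * mean(abs(corner)) / sqrt(pi / 2)
  }
  excess <- abs(op) - ip
  frac <- mean(excess > tau)
  if (frac > maxViolate)
    stop(sprintf(
      "opposed-phase magnitude exceeds in-phase beyond tolerance %.3g in %.1f%% of voxels; input may not be phase-corrected",
      tau, 100 * frac))
  if (frac > 0)
    .logMsg("IP >= |OP| violated within tolerance in %.3f%% of voxels",
            100 * frac)
  structure(list(inPhase = inPhase,
                 opposedPhase = imageVolume(op, opposedPhase@geometry,
                                            "opposed_phase"),
                 tau = tau),
            class = "DixonPair")
}

#' Two-point Dixon water/fat reconstruction
#'
#' Applies the standard 2-point identities `water = (IP + OP) / 2` and
#' `fat = (IP - OP) / 2`.  The two outputs are derived so that
#' `water + fat == inPhase` holds bit-exactly voxel-wise (fat is
#' re-derived as `IP - water` after rounding); negative intermediate
#' values, which arise from magnitude noise, are clipped to zero after
#' that conservation check unless `clip = FALSE`.
#'
#' @param pair A `"DixonPair"` from [dixonPair()].
#' @param clip Clip negative water/fat values to zero.
#' @return A list with [ImageVolume-class] elements `water` and `fat`.
#' @examples
#' g <- voxelGeometry(2, 2, 5, 1)
#' ip <- imageVolume(array(100, c(4, 4, 1)), g, "in_phase")
#' op <- imageVolume(array(20, c(4, 4, 1)), g, "opposed_phase")
#' wf <- reconstructWaterFat(dixonPair(ip, op))
#' wf$fat@data[1, 1, 1]    # 40
#' wf$water@data[1, 1, 1]  # 60
#' @export
reconstructWaterFat <- function(pair, clip = TRUE) {
  stopifnot(inherits(pair, "DixonPair"))
  ip <- pair$inPhase@data
  op <- pair$opposedPhase@data
  ## fat re-derived from the rounded water so water + fat == ip bit-exactly
  fat <- (ip - op) / 2
  water <- ip - fat
  fat <- ip - water
  if (clip) {
    fat[fat < 0] <- 0
    water[water < 0] <- 0
  }
  g <- pair$inPhase@geometry
  list(water = imageVolume(water, g, "water_only"),
       fat = imageVolume(fat, g, "fat_only"))
}

#' Voxel-wise fat fraction
#'
#' `FF = fat / (fat + water)`, with voxels of zero total signal mapped
#' to 0.  Values are confined to \[0, 1\].
#'
#' @param fat,water [ImageVolume-class] objects of identical geometry.
#' @return An [ImageVolume-class] (label `"other"`).
#' @export
fatFraction <- function(fat, water) {
  stopifnot(is(fat, "ImageVolume"), is(water, "ImageVolume"))
  .checkSameGeometry(fat, water, "fat and water")
  tot <- fat@data + water@data
  ff <- ifelse(tot == 0, 0, fat@data / tot)
  ff[ff < 0] <- 0
  ff[ff > 1] <- 1
  imageVolume(ff, fat@geometry, "other")
}
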