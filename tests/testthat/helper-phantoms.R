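## Small, fast phantom configurations for unit tests, plus a session-level
## cache so expensive phantoms are generated once per test run.

.phantomCache <- new.env(parent = emptyenv())

cachedPhantom <- function(key, specFun, seed = 1L, centralCount = 30L) {
  if (!exists(key, envir = .phantomCache)) {
    assign(key, generatePhantom(specFun(), seed = seed,
                                centralCount = centralCount),
           envir = .phantomCache)
  }
  get(key, envir = .phantomCache)
}

## ~160 x 120 x 40 grid at 1.5 x 1.5 x 3 mm: one ellipse body, thick SAT
## ring, two well-separated blobs, marrow feature; generates in < 1 s
smallSpec <- function(noiseSd = 0, satThickness = 26,
                      marrow = list(semiAxes = c(11, 8), marrowRadius = 5),
                      vatBlobs = list(
                        list(center = c(28, 2, -8), radii = c(26, 14, 18)),
                        list(center = c(-28, -4, 10), radii = c(24, 13, 16))),
                      ...) {
  phantomSpec(geometry = voxelGeometry(1.5, 1.5, 3, 40L),
              nx = 160L, ny = 120L,
              bodySemiAxes = c(105, 78),
              satThickness = satThickness,
              vatBlobs = vatBlobs,
              organs = list(list(center = c(0, 24), semiAxes = c(16, 10),
                                 signal = 350)),
              marrow = marrow,
              noiseSd = noiseSd,
              l4l5Index = 20L,
              ...)
}

smallRoi <- function() roiSpec(20L, halfWidth = 12L, centralCount = 14L)

segmentSmall <- function(ph, thr = thresholdSpec()) {
  segmentAbdomen(ph$fatOnly, ph$pair$inPhase, roi = smallRoi(), thr = thr)
}
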