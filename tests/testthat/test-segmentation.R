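test_that("ROI selection yields the documented 51-slice window", {
  g <- voxelGeometry(1.25, 1.25, 3, 150L)
  arr <- array(0, c(4L, 4L, 150L))
  arr[1, 1, ] <- 0:149  # tag every slice with its 0-based index
  v <- imageVolume(arr, g)
  roi <- roiSpec(75L)
  sub <- selectRoi(v, roi)
  expect_identical(nSlices(sub), 51L)
  expect_equal(sub@data[1, 1, ], 50:100)  # indices 50..100 inclusive

  ## degenerate half-width: the single anchor slice
  one <- selectRoi(v, roiSpec(75L, halfWidth = 0L, centralCount = 1L))
  expect_identical(nSlices(one), 1L)
  expect_equal(one@data[1, 1, 1], 75)

  ## insufficient margin names the deficit
  expect_error(selectRoi(v, roiSpec(10L)), "15 more slice")
  expect_error(selectRoi(v, roiSpec(140L)), "16 more slice")
})

test_that("body mask recovers an analytic ellipse to within 1% and fails on air", {
  ## single-material elliptical body, zero noise, fine in-plane grid
  spec <- phantomSpec(geometry = voxelGeometry(1.25, 1.25, 3, 6L),
                      nx = 256L, ny = 176L,
                      bodySemiAxes = c(150, 100), satThickness = 12,
                      vatBlobs = list(), organs = list(), marrow = NULL,
                      noiseSd = 0, l4l5Index = 3L)
  ph <- generatePhantom(spec, seed = 1, centralCount = 3L)
  body <- buildBodyMask(ph$pair$inPhase)
  areaTrue <- pi * 150 * 100
  for (k in seq_len(6)) {
    areaEst <- sum(body@data[, , k]) * 1.25 * 1.25
    expect_lt(abs(areaEst - areaTrue) / areaTrue, 0.01)
  }
  expect_error(buildBodyMask(imageVolume(array(0, c(8, 8, 2)),
                                         voxelGeometry(1, 1, 1, 2L))),
               "slice 0")
})

test_that("interior air pockets are filled into the body mask", {
  arr <- array(0, c(40L, 40L, 2L))
  xs <- (seq_len(40) - 20.5); ys <- (seq_len(40) - 20.5)
  inside <- outer(xs^2 / 18^2, ys^2 / 15^2, "+") <= 1
  arr[, , 1][inside] <- 100
  arr[, , 2][inside] <- 100
  arr[19:20, 19:20, ] <- 0  # air pocket
  v <- imageVolume(arr, voxelGeometry(1, 1, 1, 2L), "in_phase")
  body <- buildBodyMask(v)
  expect_identical(unique(as.vector(body@data[19:20, 19:20, ])), 1L)
})

test_that("fat thresholding is exact for separable intensities and warns sensibly", {
  ph <- cachedPhantom("small0", function() smallSpec(noiseSd = 0),
                      centralCount = 14L)
  fatRoi <- selectRoi(ph$fatOnly, smallRoi())
  bodyRoi <- selectRoi(ph$truth@body, smallRoi())
  ## fixed threshold at 500 between the two intensity classes: the fat
  ## mask must match the >= 50% occupancy truth support exactly
  fm <- buildFatMask(fatRoi, bodyRoi,
                     thresholdSpec("fixed", 500),
                     segmentationParams(fatOpenRadius = 0L))
  truthRoi <- selectRoi(ph$truth@fat, smallRoi())
  expect_identical(fm@data, truthRoi@data)

  ## zero fat signal inside the body: empty mask with a warning
  zero <- imageVolume(array(0, dim(fatRoi@data)), fatRoi@geometry,
                      "fat_only")
  expect_warning(fmz <- buildFatMask(zero, bodyRoi),
                 "constant|empty")
  expect_identical(sum(fmz@data), 0L)

  ## fixed threshold below the noise-background mode is flagged
  phN <- cachedPhantom("smallNoisy", function() smallSpec(noiseSd = 50),
                       centralCount = 14L)
  fatN <- selectRoi(phN$fatOnly, smallRoi())
  bodyN <- buildBodyMask(selectRoi(phN$pair$inPhase, smallRoi()))
  expect_warning(buildFatMask(fatN, bodyN, thresholdSpec("fixed", 1)),
                 "background mode")
})

test_that("Otsu fat mask stays accurate under moderate noise", {
  ph <- cachedPhantom("smallNoisy", function() smallSpec(noiseSd = 50),
                      centralCount = 14L)
  seg <- segmentSmall(ph)
  truthRoi <- selectRoi(ph$truth@fat, smallRoi())
  d <- diceCoefficient(seg$result@fat, truthRoi)
  expect_gte(d, 0.95)
})

test_that("SAT/VAT separation is exact on a zero-noise phantom", {
  ph <- cachedPhantom("small0", function() smallSpec(noiseSd = 0),
                      centralCount = 14L)
  seg <- segmentSmall(ph)
  satT <- selectRoi(ph$truth@sat, smallRoi())
  vatT <- selectRoi(ph$truth@vat, smallRoi())
  ## boundary partial-volume voxels differ by construction; interior
  ## agreement must be exact, so Dice is essentially 1
  expect_gte(diceCoefficient(seg$result@sat, satT), 0.97)
  expect_gte(diceCoefficient(seg$result@vat, vatT), 0.97)
  ## no cross-talk: SAT stays out of the cavity, VAT out of the shell
  expect_identical(sum(seg$result@sat@data * seg$result@vat@data), 0L)
})

test_that("a zero-thickness ring leaves SAT empty and sends interior fat to VAT", {
  body <- array(0L, c(40L, 40L, 3L))
  fat <- array(0L, c(40L, 40L, 3L))
  xs <- seq_len(40) - 20.5
  inside <- outer(xs^2 / 18^2, xs^2 / 16^2, "+") <= 1
  blob <- outer((xs - 3)^2 / 5^2, xs^2 / 4^2, "+") <= 1
  for (k in 1:3) {
    body[, , k][inside] <- 1L
    fat[, , k][blob] <- 1L
  }
  g <- voxelGeometry(1, 1, 1, 3L)
  expect_warning(
    res <- splitSatVat(maskVolume(fat, g, "fat"), maskVolume(body, g, "body")),
    "SAT is empty")
  expect_identical(sum(res@sat@data), 0L)
  expect_identical(res@vat@data, fat)
})

test_that("marrow fat is counted in TAT but in neither SAT nor VAT", {
  ph <- cachedPhantom("small0", function() smallSpec(noiseSd = 0),
                      centralCount = 14L)
  seg <- segmentSmall(ph)
  vols <- seg$volumes
  expect_gt(vols@tatMl, vols@vatMl + vols@satMl + 1)  # marrow-sized gap
  ## the marrow disc itself: fat-positive, SAT/VAT-negative
  satT <- selectRoi(ph$truth@sat, smallRoi())@data
  vatT <- selectRoi(ph$truth@vat, smallRoi())@data
  fatA <- seg$result@fat@data
  satA <- seg$result@sat@data
  vatA <- seg$result@vat@data
  marrowish <- fatA == 1L & satT == 0L & vatT == 0L
  expect_gt(sum(marrowish), 0)
  expect_identical(sum(satA[marrowish]), 0L)
  expect_identical(sum(vatA[marrowish]), 0L)
})

test_that("volume computation follows the voxel arithmetic and slab conventions", {
  ## 1000 voxels at 1.25 x 1.25 x 3 mm^3 = 4.6875 mL
  g <- voxelGeometry(1.25, 1.25, 3, 5L)
  arr <- array(0L, c(20L, 20L, 5L))
  arr[1:10, 1:20, 1:5] <- 1L  # 200 voxels per slice x 5 slices
  m <- maskVolume(arr, g, "fat")
  empty <- maskVolume(array(0L, dim(arr)), g)
  res <- new("SegmentationResult", body = m, fat = m, sat = empty,
             vat = empty, cavity = empty,
             roi = roiSpec(2L, 2L, 5L), params = segmentationParams())
  expect_equal(computeVolumes(res)@tatMl, 1000 * 4.6875 / 1000)

  ## the central-slab window is the documented asymmetric one
  expect_equal(adiposeg:::.centralWindow(25L, 30L), c(11L, 41L))
  expect_equal(adiposeg:::.centralWindow(2L, 4L), c(1L, 5L))
  expect_error(computeVolumes(res, centralCount = 9L), "exceeds")

  ## empty masks give all-zero volumes with the 0/0 ratio convention
  res0 <- new("SegmentationResult", body = empty, fat = empty, sat = empty,
              vat = empty, cavity = empty,
              roi = roiSpec(2L, 2L, 5L), params = segmentationParams())
  v0 <- computeVolumes(res0)
  expect_equal(v0@tatMl, 0)
  expect_equal(v0@vatSatRatio, 0)
})

test_that("volumes scale exactly with slice thickness", {
  ph <- cachedPhantom("small0", function() smallSpec(noiseSd = 0),
                      centralCount = 14L)
  seg <- segmentSmall(ph)
  v1 <- computeVolumes(seg$result)
  res2 <- seg$result
  g <- res2@body@geometry
  g2 <- voxelGeometry(g@dx, g@dy, 2 * g@dz, g@nSlices)
  for (s in c("body", "fat", "sat", "vat", "cavity")) {
    m <- slot(res2, s); m@geometry <- g2; slot(res2, s) <- m
  }
  v2 <- computeVolumes(res2)
  expect_identical(v2@vatMl, 2 * v1@vatMl)
  expect_identical(v2@satMl, 2 * v1@satMl)
  expect_identical(v2@tatMl, 2 * v1@tatMl)
  expect_identical(v2@abdominalMl, 2 * v1@abdominalMl)
})

test_that("lowering a fixed fat threshold never decreases TAT", {
  ph <- cachedPhantom("smallNoisy", function() smallSpec(noiseSd = 50),
                      centralCount = 14L)
  fatRoi <- selectRoi(ph$fatOnly, smallRoi())
  ipRoi <- selectRoi(ph$pair$inPhase, smallRoi())
  body <- buildBodyMask(ipRoi)
  tats <- vapply(c(800, 600, 400, 250), function(thr) {
    fm <- suppressWarnings(
      buildFatMask(fatRoi, body, thresholdSpec("fixed", thr)))
    res <- suppressWarnings(splitSatVat(fm, body, roi = smallRoi()))
    computeVolumes(res)@tatMl
  }, 0)
  expect_true(all(diff(tats) >= 0))
})
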