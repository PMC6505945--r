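mk <- function(vals, dims = c(length(vals), 1L, 1L)) {
  maskVolume(array(vals, dims), voxelGeometry(1, 1, 1, dims[3]))
}

test_that("Dice coefficient matches hand-computed and brute-force values", {
  a <- mk(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  b <- mk(c(0, 1, 1, 1, 1, 1, 1, 0, 0, 0))
  expect_equal(diceCoefficient(a, b), 0.6)  # 2*3 / (4+6)
  expect_equal(diceCoefficient(a, a), 1)
  disj <- mk(c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1))
  expect_equal(diceCoefficient(a, disj), 0)
  ## empty-vs-empty agreement convention
  e <- mk(rep(0, 10))
  expect_equal(diceCoefficient(e, e), 1)
  expect_error(diceCoefficient(a, mk(rep(1, 4))), "mismatch")

  set.seed(5)
  for (i in 1:10) {
    x <- mk(rbinom(60, 1, 0.5), c(5L, 4L, 3L))
    y <- mk(rbinom(60, 1, 0.5), c(5L, 4L, 3L))
    expect_equal(diceCoefficient(x, y), bruteDice(x@data, y@data))
    expect_equal(diceCoefficient(x, y), diceCoefficient(y, x))  # symmetry
  }
})

test_that("Bland-Altman statistics follow their definitions", {
  ## identical series: zero bias with a degenerate CI
  x <- c(10, 12, 14, 9, 11, 13, 10, 12, 11, 10)
  ba0 <- blandAltman(x, x)
  expect_equal(ba0@bias, 0)
  expect_equal(ba0@ci, c(0, 0))
  expect_equal(ba0@loa, c(0, 0))

  ## constant offset: bias -5 with zero spread
  ba5 <- blandAltman(x, x + 5)
  expect_equal(ba5@bias, -5)
  expect_equal(ba5@sdDiff, 0)

  ## random pairs: bias equals the difference of means (direct summation),
  ## CI uses the t quantile with n - 1 df
  set.seed(7)
  a <- rnorm(10, 100, 12); b <- rnorm(10, 95, 10)
  ba <- blandAltman(a, b)
  expect_equal(ba@bias, sum(a) / 10 - sum(b) / 10)
  d <- a - b
  expect_equal(ba@sdDiff, sqrt(sum((d - mean(d))^2) / 9))
  expect_equal(ba@ci[2] - ba@bias, qt(0.975, 9) * ba@sdDiff / sqrt(10))
  expect_equal(ba@loa, ba@bias + c(-1.96, 1.96) * ba@sdDiff)

  ## swapping the inputs negates bias and mirrors the limits
  ba2 <- blandAltman(b, a)
  expect_equal(ba2@bias, -ba@bias)
  expect_equal(ba2@loa, -rev(ba@loa))
  expect_equal(ba2@ci, -rev(ba@ci))

  expect_error(blandAltman(1, 2), "at least 2")
})

test_that("self-comparison of a segmentation gives perfect agreement", {
  ph <- cachedPhantom("small0", function() smallSpec(noiseSd = 0),
                      centralCount = 14L)
  seg <- segmentSmall(ph)
  rep <- compareSegmentations(seg$result,
                              list(sat = seg$result@sat,
                                   vat = seg$result@vat,
                                   tat = seg$result@fat,
                                   body = seg$result@body))
  expect_true(all(abs(rep@dice - 1) < 1e-12))
  expect_equal(volumeTable(rep@volumesAuto), volumeTable(rep@volumesRef))
})

test_that("an eroded reference lowers Dice and biases the volume", {
  ph <- cachedPhantom("small0", function() smallSpec(noiseSd = 0),
                      centralCount = 14L)
  seg <- segmentSmall(ph)
  vat <- seg$result@vat
  er <- EBImage::erode(vat@data, EBImage::makeBrush(3, "disc"))
  storage.mode(er) <- "integer"
  refVat <- maskVolume(er, vat@geometry, "VAT")
  rep <- suppressWarnings(
    compareSegmentations(seg$result, list(vat = refVat)))
  expect_lt(rep@dice[["vat"]], 1)
  ## reference (eroded) minus auto is negative: auto VAT is larger
  expect_lt(rep@volumesRef@vatMl, rep@volumesAuto@vatMl)
})

test_that("missing reference regions yield a partial report with warning", {
  ph <- cachedPhantom("small0", function() smallSpec(noiseSd = 0),
                      centralCount = 14L)
  seg <- segmentSmall(ph)
  expect_warning(rep <- compareSegmentations(seg$result,
                                             list(vat = seg$result@vat)),
                 "lacks region")
  expect_identical(names(rep@dice), "vat")
})

test_that("cohort aggregation averages Dice and runs Bland-Altman per region", {
  ph <- cachedPhantom("small0", function() smallSpec(noiseSd = 0),
                      centralCount = 14L)
  seg <- segmentSmall(ph)
  ref <- list(sat = selectRoi(ph$truth@sat, smallRoi()),
              vat = selectRoi(ph$truth@vat, smallRoi()),
              tat = selectRoi(ph$truth@fat, smallRoi()))
  r1 <- compareSegmentations(seg$result, ref)
  coh <- cohortValidation(list(r1, r1, r1))
  expect_equal(coh@dice, r1@dice)
  expect_identical(sort(names(coh@blandAltman)),
                   sort(c("vat", "sat", "tat", "abdominal")))
  for (rg in c("vat", "sat", "tat"))
    expect_equal(coh@blandAltman[[rg]]@sdDiff, 0)
})
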