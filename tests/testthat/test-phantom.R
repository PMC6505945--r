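test_that("closed-form volumes match independent hand calculations", {
  ## plain ring, no vertebra: pi (ab - (a-t)(b-t)) x slab height
  spec <- phantomSpec(bodySemiAxes = c(150, 100), satThickness = 10,
                      vatBlobs = list(), organs = list(), marrow = NULL,
                      noiseSd = 0)
  av <- analyticVolumes(spec)
  expect_equal(av@satMl, pi * (150 * 100 - 140 * 90) * 90 / 1000,
               tolerance = 1e-12)
  expect_equal(av@satMl, 678.584, tolerance = 1e-4)
  expect_equal(av@abdominalMl, pi * 150 * 100 * 90 / 1000, tolerance = 1e-12)
  expect_equal(av@vatMl, 0)

  ## zero ring thickness: no SAT anywhere
  spec0 <- phantomSpec(satThickness = 0, vatBlobs = list(), organs = list(),
                       marrow = NULL, noiseSd = 0)
  expect_equal(analyticVolumes(spec0)@satMl, 0)

  ## a sphere fully inside the slab: (4/3) pi r^3
  specS <- phantomSpec(bodySemiAxes = c(150, 100), satThickness = 10,
                       vatBlobs = list(list(center = c(0, 0, 0), radii = 30)),
                       organs = list(), marrow = NULL, noiseSd = 0)
  expect_equal(analyticVolumes(specS)@vatMl, 4 / 3 * pi * 30^3 / 1000,
               tolerance = 1e-12)  # 113.10 mL
})

test_that("volumes obey the cubic scaling law", {
  spec1 <- phantomSpec(bodySemiAxes = c(80, 60), satThickness = 10,
                       vatBlobs = list(list(center = c(0, 10, 0),
                                            radii = c(20, 12, 15))),
                       organs = list(), marrow = NULL, noiseSd = 0,
                       geometry = voxelGeometry(1.25, 1.25, 3, 150L))
  ## doubling every linear dimension (including slice thickness, so the
  ## slab height doubles too) multiplies volumes by 8
  spec2 <- phantomSpec(bodySemiAxes = c(160, 120), satThickness = 20,
                       vatBlobs = list(list(center = c(0, 20, 0),
                                            radii = c(40, 24, 30))),
                       organs = list(), marrow = NULL, noiseSd = 0,
                       geometry = voxelGeometry(1.25, 1.25, 6, 150L))
  v1 <- analyticVolumes(spec1)
  v2 <- analyticVolumes(spec2)
  expect_equal(v2@satMl, 8 * v1@satMl, tolerance = 1e-10)
  expect_equal(v2@vatMl, 8 * v1@vatMl, tolerance = 1e-10)
  expect_equal(v2@abdominalMl, 8 * v1@abdominalMl, tolerance = 1e-10)
})

test_that("voxelised truth agrees with analytic volumes within the surface bound", {
  ph <- cachedPhantom("small0", function() smallSpec(noiseSd = 0),
                      centralCount = 14L)
  vv <- voxelVolume(ph$fatOnly) / 1000
  tr <- ph$truth
  for (r in c("vat", "sat", "tat", "body")) {
    fld <- c(vat = "vatMl", sat = "satMl", tat = "tatMl",
             body = "abdominalMl")[[r]]
    err <- abs(slot(tr@volumes, fld) - slot(tr@analytic, fld))
    expect_lte(err, tr@surfaceVoxels[[r]] * vv)
  }
})

test_that("spherical blob voxelisation is within one surface layer of analytic", {
  spec <- phantomSpec(geometry = voxelGeometry(1.25, 1.25, 3, 40L),
                      nx = 160L, ny = 120L,
                      bodySemiAxes = c(90, 65), satThickness = 10,
                      vatBlobs = list(list(center = c(0, 0, 0), radii = 30)),
                      organs = list(), marrow = NULL, noiseSd = 0,
                      l4l5Index = 20L)
  ph <- generatePhantom(spec, seed = 1)
  vv <- voxelVolume(ph$fatOnly) / 1000
  analytic <- 4 / 3 * pi * 30^3 / 1000
  expect_equal(ph$truth@analytic@vatMl, analytic, tolerance = 1e-10)
  expect_lte(abs(ph$truth@volumes@vatMl - analytic),
             ph$truth@surfaceVoxels[["vat"]] * vv)
})

test_that("generation is deterministic in the seed and varies only in noise", {
  spec <- smallSpec(noiseSd = 40)
  a <- generatePhantom(spec, seed = 9, centralCount = 14L)
  b <- generatePhantom(spec, seed = 9, centralCount = 14L)
  expect_identical(a$pair$inPhase@data, b$pair$inPhase@data)
  expect_identical(a$fatOnly@data, b$fatOnly@data)
  c_ <- generatePhantom(spec, seed = 10, centralCount = 14L)
  expect_false(identical(a$fatOnly@data, c_$fatOnly@data))
  ## truth masks are noise-independent
  expect_identical(a$truth@fat@data, c_$truth@fat@data)
  expect_identical(a$truth@volumes, c_$truth@volumes)
})

test_that("zero ring thickness gives zero SAT ground truth", {
  spec <- smallSpec(satThickness = 0, marrow = NULL)
  ph <- generatePhantom(spec, seed = 1, centralCount = 14L)
  expect_identical(sum(ph$truth@sat@data), 0L)
  expect_gt(sum(ph$truth@vat@data), 0L)
})

test_that("blob placement violating clearances is rejected with named offenders", {
  ## blob reaching into the SAT ring
  expect_error(
    phantomSpec(vatBlobs = list(list(center = c(0, 60, 0), radii = 30)),
                marrow = NULL),
    "blob 1")
  ## overlapping blobs
  expect_error(
    phantomSpec(vatBlobs = list(list(center = c(0, 0, 0), radii = 30),
                                list(center = c(20, 5, 5), radii = 30)),
                marrow = NULL),
    "blobs 1 and 2")
  ## marrow that cannot fit inside the ring
  expect_error(
    phantomSpec(satThickness = 12,
                marrow = list(semiAxes = c(18.2, 13), marrowRadius = 8),
                vatBlobs = list()),
    "marrow")
})

test_that("randomised cohort specs stay inside the study envelope", {
  sp <- randomPhantomSpec(3)
  expect_identical(randomPhantomSpec(3)@vatBlobs, sp@vatBlobs)  # deterministic
  expect_true(length(sp@vatBlobs) >= 3 && length(sp@vatBlobs) <= 6)
  av <- analyticVolumes(sp)
  expect_true(av@vatMl >= 700 && av@vatMl <= 1400)
  expect_true(av@satMl >= 1100 && av@satMl <= 3900)
})
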