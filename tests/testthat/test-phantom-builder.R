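test_that("a torso-only spec yields a pure soft-tissue body", {
  spec <- phantomSpec(1.70, 70, spacing = c(10, 10, 10), organs = FALSE,
                      forceWeightKg = NA)
  ph <- buildPhantom(spec)
  codes <- voxelData(ph)
  expect_gt(sum(codes > 0L), 0)
  expect_setequal(unique(as.vector(codes)), c(0L, 1L))
})

test_that("organ volumes are realised to within one voxel volume", {
  ## clinical-resolution voxels (20.787 mm^3) on a reduced grid
  spec <- phantomSpec(1.70, 70, spacing = c(2.73, 2.73, 2.79),
                      grid = c(128, 128), organs = FALSE,
                      forceWeightKg = NA)
  spec$heightM <- 0.55          # short torso-only scene to keep it small
  spec$torso$z <- c(0, 540)
  spec$legs <- NULL; spec$head <- NULL
  spec$organs <- list(liver = list(code = 3L, volumeMl = 1500,
                                   centre = c(spec$torso$cx, spec$torso$cy,
                                              270),
                                   ratios = c(1.6, 1.2, 1.0)))
  ph <- buildPhantom(spec)
  vvoxMl <- voxelVolumeMl(ph)
  nLiver <- sum(voxelData(ph) == 3L)
  expect_lte(abs(nLiver * vvoxMl - 1500), vvoxMl)
})

test_that("building is deterministic for a fixed spec", {
  spec <- phantomSpec(1.65, 80, spacing = c(8, 8, 8))
  expect_identical(voxelData(buildPhantom(spec)),
                   voxelData(buildPhantom(spec)))
})

test_that("misplaced or oversized organs raise informative errors", {
  spec <- phantomSpec(1.70, 70, spacing = c(10, 10, 10), organs = FALSE)
  spec$organs <- list(liver = list(code = 3L, volumeMl = 500,
                                   centre = c(5, 5, 5),
                                   ratios = c(1, 1, 1)))
  expect_error(buildPhantom(spec), "liver")
  spec$organs <- list(liver = list(code = 3L, volumeMl = 60000,
                                   centre = c(spec$torso$cx, spec$torso$cy,
                                              mean(spec$torso$z)),
                                   ratios = c(1, 1, 1)))
  expect_error(buildPhantom(spec), "liver")
})

test_that("the default cohort spans the published BMI range in order", {
  coh <- generateCohort(spacing = c(8, 8, 8))
  expect_length(coh, 8L)
  bmis <- vapply(coh, function(p) {
    m <- computeBodyMetrics(p)
    m@bmi
  }, numeric(1))
  expect_true(all(diff(bmis) >= 0))
  expect_identical(round(min(bmis)), 19)
  ## the largest phantom computes to BMI 37.45 from the published
  ## height/weight (reported rounded as 38)
  expect_identical(round(max(bmis)), 37)
})

test_that("a two-phantom cohort at fixed BMI reproduces that BMI", {
  coh <- generateCohort(n = 2, heights = c(1.65, 1.75), bmiRange = c(25, 25),
                        spacing = c(10, 10, 10), organs = FALSE)
  bmis <- vapply(coh, function(p) computeBodyMetrics(p)@bmi, numeric(1))
  expect_identical(round(bmis), c(P1 = 25, P2 = 25))
})

test_that("cohort generation is deterministic", {
  a <- generateCohort(n = 2, heights = c(1.6, 1.8), weights = c(60, 90),
                      spacing = c(12, 12, 12), organs = FALSE)
  b <- generateCohort(n = 2, heights = c(1.6, 1.8), weights = c(60, 90),
                      spacing = c(12, 12, 12), organs = FALSE)
  expect_identical(lapply(a, voxelData), lapply(b, voxelData))
})

test_that("body metrics: forced weight, BSA, BMI and voxel-mass weight", {
  ## forced weight reproduces the published P1 BSA
  ph <- buildPhantom(phantomSpec(1.73, 56, spacing = c(6, 6, 6)))
  m <- computeBodyMetrics(ph)
  expect_equal(m@weightKg, 56, tolerance = 1e-6)
  expect_equal(round(m@bsaM2, 2), 1.67)
  ## the published P7 habitus rounds to BMI 37
  expect_identical(round(bodyMassIndex(86, 1.53)), 37)
  ## 1000 voxels of 1 mL at density 1 g/cm^3 weigh exactly 1 kg
  ph2 <- boxPhantom(dim = c(10, 10, 10), spacing = c(10, 10, 10))
  tb <- defaultStructureTable()
  tb@table$density_g_cm3[tb@table$code == 1L] <- 1.0
  expect_equal(computeBodyMetrics(ph2, tb)@weightKg, 1.0, tolerance = 1e-9)
})

test_that("zero body mask raises an error", {
  ph <- boxPhantom(code = 1L)
  ph@codes[] <- 0L
  expect_error(computeBodyMetrics(ph), "empty body mask")
})

test_that("measured circumference matches the analytic perimeter", {
  ph <- cylinderPhantom(radiusMm = 100, spacing = c(2, 2, 4))
  m <- computeBodyMetrics(ph)
  expect_lt(abs(m@circumferenceCm - 2 * pi * 10), 1)  # 62.8 +- 1 cm
})

test_that("scaling the cross-section scales the circumference linearly", {
  m1 <- computeBodyMetrics(cylinderPhantom(radiusMm = 80))
  m2 <- computeBodyMetrics(cylinderPhantom(radiusMm = 80 * 1.4))
  expect_equal(m2@circumferenceCm / m1@circumferenceCm, 1.4,
               tolerance = 0.02)
})

test_that("weight is additive in painted structures", {
  ph <- boxPhantom(dim = c(12, 12, 12), spacing = c(10, 10, 10))
  tb <- defaultStructureTable()
  w0 <- computeBodyMetrics(ph, tb)@weightKg
  ## add 100 voxels (0.1 L) of spleen at 1.06 g/cm3
  ph2 <- ph
  ph2@codes[1:100] <- 4L
  w1 <- computeBodyMetrics(ph2, tb)@weightKg
  dens <- tb@table$density_g_cm3
  expect_equal(w1 - w0, 100 * 1 * (dens[tb@table$code == 4L] -
                                   dens[tb@table$code == 1L]) / 1000,
               tolerance = 1e-9)
})

test_that("phantom NIfTI round trip preserves the object", {
  ph <- buildPhantom(phantomSpec(1.6, 60, spacing = c(12, 12, 12),
                                 organs = FALSE))
  path <- tempfile(fileext = ".nii.gz")
  writePhantom(ph, path)
  ph2 <- readPhantom(path)
  expect_identical(voxelData(ph2), voxelData(ph))
  expect_equal(voxelSpacing(ph2), voxelSpacing(ph))
  expect_equal(ph2@densityScale, ph@densityScale)
  expect_identical(imagedRange(ph2), imagedRange(ph))
  unlink(c(path, sub("\\.nii\\.gz$", ".json", path)))
})

test_that("structure table CSV round trip and lookups", {
  tb <- defaultStructureTable()
  path <- tempfile(fileext = ".csv")
  writeStructureTable(tb, path)
  tb2 <- readStructureTable(path)
  expect_equal(tb2@table, tb@table)
  expect_equal(structureSuv(tb, 3L), 9.5)
  expect_equal(structureDensity(tb, c(3L, 4L)), c(1.06, 1.06))
  expect_error(structureSuv(tb, 99L), "99")
  unlink(path)
})
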