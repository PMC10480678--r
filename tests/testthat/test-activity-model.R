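test_that("the 68Ga decay factor follows the half-life law", {
  expect_identical(decayFactor(0), 1)
  expect_equal(decayFactor(67.71), 0.5, tolerance = 1e-12)
  expect_equal(decayFactor(60), 0.541, tolerance = 5e-4)
  expect_error(decayFactor(-1), "non-negative")
  ## multiplicative over intervals
  for (t1 in c(5, 30, 111)) for (t2 in c(0, 17, 60))
    expect_equal(decayFactor(t1 + t2), decayFactor(t1) * decayFactor(t2),
                 tolerance = 1e-12)
})

test_that("activity painting follows A_inj * SUV * V_vox / w_T", {
  ## liver-only box at clinical voxel resolution, weight forced to 56 kg
  ph <- boxPhantom(dim = c(8, 8, 8), spacing = c(2.73, 2.73, 2.79),
                   code = 3L)
  am <- paintActivity(ph, injectedMBq = 112, applyDecay = FALSE,
                      weightKg = 56)
  expect_equal(voxelData(am)[1], 394.9, tolerance = 1e-3)
  ## zero SUV structure paints zero
  tb <- defaultStructureTable()
  tb@table$suv[tb@table$code == 3L] <- 0
  am0 <- paintActivity(ph, tb, injectedMBq = 112, applyDecay = FALSE,
                       weightKg = 56)
  expect_true(all(voxelData(am0) == 0))
  ## zero injected activity paints zero
  amz <- paintActivity(ph, injectedMBq = 0, weightKg = 56)
  expect_true(all(voxelData(amz) == 0))
  ## linearity in the injected activity
  am2 <- paintActivity(ph, injectedMBq = 224, applyDecay = FALSE,
                       weightKg = 56)
  expect_equal(voxelData(am2), 2 * voxelData(am))
  ## unknown code errors by name
  ph@codes[1] <- 77L
  expect_error(paintActivity(ph, injectedMBq = 1, weightKg = 56), "77")
})

test_that("a 1500 mL liver at SUV 9.5 in a 56 kg body holds 25.45%", {
  ## fraction of injected activity in a structure = SUV * V / w
  sp <- c(5, 5, 5)
  nLiver <- round(1500 / (prod(sp) / 1000))
  dim <- c(30, 30, 30)
  ph <- boxPhantom(dim = dim, spacing = sp, code = 1L)
  ph@codes[seq_len(nLiver)] <- 3L
  am <- paintActivity(ph, injectedMBq = 100, applyDecay = FALSE,
                      weightKg = 56)
  liverBq <- sum(voxelData(am)[voxelData(ph) == 3L])
  expect_equal(liverBq / (100e6), 9.5 * 1500 / 56000, tolerance = 1e-3)
  ## structure fractions are independent of the injected activity
  am2 <- paintActivity(ph, injectedMBq = 250, applyDecay = FALSE,
                       weightKg = 56)
  expect_equal(sum(voxelData(am2)[voxelData(ph) == 3L]) / 250e6,
               liverBq / 100e6, tolerance = 1e-12)
})

test_that("imaged fraction sums the imaged range and undoes decay", {
  ph <- boxPhantom(dim = c(6, 6, 10), spacing = c(10, 10, 10))
  ph@imagedRange <- c(1L, 10L)
  am <- paintActivity(ph, injectedMBq = 50, applyDecay = FALSE,
                      weightKg = 30)
  tb <- defaultStructureTable()
  suvSoft <- structureSuv(tb, 1L)
  ## whole grid: closed form sum SUV * V / w
  expect_equal(computeImagedFraction(am, ph),
               suvSoft * (6 * 6 * 10) / 30000, tolerance = 1e-9)
  ## empty imaged range -> 0
  ph2 <- ph; ph2@imagedRange <- c(11L, 12L)
  expect_equal(computeImagedFraction(am, ph2), 0)
  ## decayed map reports the same (pre-decay) fraction
  amd <- paintActivity(ph, injectedMBq = 50, uptakeMin = 60,
                       applyDecay = TRUE, weightKg = 30)
  expect_equal(computeImagedFraction(amd, ph),
               computeImagedFraction(am, ph), tolerance = 1e-9)
})
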