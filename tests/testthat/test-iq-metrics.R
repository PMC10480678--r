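test_that("liver SNR uses the population-SD convention", {
  img <- array(0, c(3, 1, 1)); img[] <- c(90, 100, 110)
  voi <- array(TRUE, c(3, 1, 1))
  expect_equal(liverSnr(img, voi), 100 / sqrt(200 / 3), tolerance = 1e-12)
  expect_equal(round(liverSnr(img, voi), 2), 12.25)
  ## degenerate VOI errors
  img0 <- array(5, c(3, 1, 1))
  expect_error(liverSnr(img0, voi), "zero standard deviation")
})

test_that("tumour CNR and the inclusive Rose threshold", {
  set.seed(1)
  img <- array(rnorm(1000, 100, 10), c(10, 10, 10))
  voi <- array(FALSE, c(10, 10, 10)); voi[1:5, , ] <- TRUE
  tum <- array(FALSE, c(10, 10, 10)); tum[7:8, 7:8, 7:8] <- TRUE
  vals <- img[voi]; s <- sqrt(mean((vals - mean(vals))^2))
  ## equal means -> CNR 0, no rose pass
  img1 <- img; img1[tum] <- mean(vals)
  r <- tumourCnr(img1, tum, voi)
  expect_equal(r$cnr, 0, tolerance = 1e-9)
  expect_false(r$rosePass)
  ## exactly 5 sigma contrast -> rose pass (boundary included)
  img2 <- img; img2[tum] <- mean(vals) + 5 * s
  r2 <- tumourCnr(img2, tum, voi)
  expect_equal(r2$cnr, 5, tolerance = 1e-9)
  expect_true(r2$rosePass)
})

test_that("SNR/CNR affine equivariance", {
  set.seed(2)
  img <- array(rnorm(512, 50, 5), c(8, 8, 8))
  voi <- array(FALSE, c(8, 8, 8)); voi[2:6, 2:6, 2:6] <- TRUE
  tum <- array(FALSE, c(8, 8, 8)); tum[8, 8, 8] <- TRUE
  snr <- liverSnr(img, voi)
  cnr <- tumourCnr(img, tum, voi)$cnr
  ## adding a constant shifts the mean but not the SD
  expect_equal(liverSnr(img + 7, voi),
               (mean(img[voi]) + 7) / PEThabitus:::popSd(img[voi]))
  ## pure scaling leaves SNR and CNR invariant
  expect_equal(liverSnr(img * 3, voi), snr, tolerance = 1e-12)
  expect_equal(tumourCnr(img * 3, tum, voi)$cnr, cnr, tolerance = 1e-12)
})

test_that("the liver VOI sits at the inscribed-sphere centre", {
  spacing <- c(3, 3, 3)
  dims <- c(40, 40, 40)
  liver <- ellipsoidMask(dims, spacing, c(45, 40, 42),
                         centreIdx = c(20, 20, 20))
  voi <- placeLiverVoi(liver, spacing, diameterMm = 25)
  ## distance-transform oracle: brute-force max-min-distance voxel
  idx <- which(liver, arr.ind = TRUE, useNames = FALSE)
  out <- which(!liver, arr.ind = TRUE, useNames = FALSE)
  d <- PEThabitus:::minDistanceMm(idx, out, spacing)
  expect_equal(unname(d[idx[, 1] == voi$centre[1] &
                        idx[, 2] == voi$centre[2] &
                        idx[, 3] == voi$centre[3]]),
               max(d), tolerance = 1e-9)
  expect_true(all(liver[voi$mask]))
})

test_that("the VOI avoids tumours and errors when infeasible", {
  spacing <- c(3, 3, 3)
  liver <- ellipsoidMask(c(40, 40, 40), spacing, c(45, 40, 42))
  ts <- buildTumourSet(liver, spacing, targetsMl = c(0.5, 1, 2),
                       rngSeed = 2, marginMm = 6, minSeparationMm = 10)
  voi <- placeLiverVoi(liver, spacing, tumours = ts, diameterMm = 25)
  lab <- tumourLabelVolume(ts)
  expect_identical(sum(voi$mask & lab > 0L), 0L)
  ## liver smaller than the VOI -> error
  small <- ellipsoidMask(c(20, 20, 20), spacing, c(10, 9, 8))
  expect_error(placeLiverVoi(small, spacing, diameterMm = 25),
               "cannot contain")
  expect_error(placeLiverVoi(array(FALSE, c(4, 4, 4)), spacing), "empty")
})

test_that("VOI centre tie-break picks the lowest (z, y, x) maximiser", {
  spacing <- c(2, 2, 2)
  liver <- array(FALSE, c(22, 22, 22))
  liver[2:21, 2:21, 2:21] <- TRUE      # even cube: 8 tied central voxels
  v <- placeLiverVoi(liver, spacing, diameterMm = 10)
  d <- distanceToOutside(liver, spacing)
  d[!liver] <- -Inf
  ties <- which(d >= max(d) - 1e-9, arr.ind = TRUE, useNames = FALSE)
  ord <- order(ties[, 3], ties[, 2], ties[, 1])
  expect_identical(v$centre, ties[ord[1], ])
})
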