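## Acquisition model: projection, attenuation, Poisson counts, OSEM.

test_that("attenuation map applies mu_water scaled by density", {
  ph <- boxPhantom(dim = c(4, 4, 4), spacing = c(2, 2, 2), code = 1L)
  mu <- attenuationMap(ph)
  expect_equal(voxelData(mu)[1], 0.0096)   # water-density soft tissue
  ph@codes[] <- 0L
  expect_true(all(voxelData(attenuationMap(ph)) == 0))
})

test_that("a 200 mm water path transmits exp(-1.92)", {
  sc <- uniformCylinderScene(n = 80, nz = 1, spacingMm = 3, radiusMm = 100)
  af <- attenuationFactors(sc$mu, projectionAngles(4))
  central <- af[(dim(af)[1] + 1) / 2, 1, 1]
  expect_lt(abs(central - exp(-1.92)), 0.005)
})

test_that("forward and back projection are exact adjoints", {
  set.seed(1)
  x <- array(runif(40 * 40 * 2), c(40, 40, 2))
  ang <- projectionAngles(12)
  nb <- 61
  y <- array(runif(nb * 12 * 2), c(nb, 12, 2))
  lhs <- sum(radonTransform(x, ang, nb) * y)
  rhs <- sum(x * backProject(y, 40, 40, ang))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("simulated counts obey the expected-count bookkeeping", {
  sc <- uniformCylinderScene(n = 48, nz = 2, spacingMm = 6, radiusMm = 100,
                             bqPerVoxel = 20)
  ang <- projectionAngles(16)
  ## zero activity -> zero sinogram
  act0 <- sc$activity; act0@data[] <- 0
  s0 <- simulateCounts(act0, sc$mu, tMin = 1, sensitivity = 1e-3,
                       backgroundFraction = 0, rngSeed = 1, angles = ang)
  expect_true(all(s0@counts == 0))
  ## with mu = 0 and b = 0, total expectation = s * t * sum(A) * nAngles
  mu0 <- sc$mu; mu0@data[] <- 0
  sE <- simulateCounts(sc$activity, mu0, tMin = 2, sensitivity = 1e-3,
                       backgroundFraction = 0, rngSeed = 1, angles = ang,
                       noise = FALSE)
  expect_equal(sum(sE@counts),
               1e-3 * 2 * sum(sc$activity@data) * length(ang),
               tolerance = 1e-6)
  ## doubling t doubles the expectation; empirical means agree within 3
  ## sigma of the Poisson error over repeated draws
  tot <- function(tMin, seeds) vapply(seeds, function(sd)
    sum(simulateCounts(sc$activity, sc$mu, tMin = tMin,
                       sensitivity = 2e-4, backgroundFraction = 0,
                       rngSeed = sd, angles = ang)@counts), numeric(1))
  m1 <- tot(1, 1:50); m2 <- tot(2, 51:100)
  expE1 <- sum(simulateCounts(sc$activity, sc$mu, tMin = 1,
                              sensitivity = 2e-4, backgroundFraction = 0,
                              rngSeed = 1, angles = ang,
                              noise = FALSE)@counts)
  expect_lt(abs(mean(m1) - expE1), 3 * sqrt(expE1 / 50))
  expect_lt(abs(mean(m2) - 2 * expE1), 3 * sqrt(2 * expE1 / 50))
  ## reproducibility per seed
  expect_identical(
    simulateCounts(sc$activity, sc$mu, rngSeed = 9, angles = ang)@counts,
    simulateCounts(sc$activity, sc$mu, rngSeed = 9, angles = ang)@counts)
  ## mismatched grids error
  muBad <- methods::new("MuMap", data = array(0, c(10, 10, 2)),
                        spacing = sc$spacing)
  expect_error(simulateCounts(sc$activity, muBad), "do not match")
})

test_that("the background term contributes the configured fraction", {
  sc <- uniformCylinderScene(n = 48, nz = 2, spacingMm = 6, radiusMm = 100)
  ang <- projectionAngles(16)
  sE <- simulateCounts(sc$activity, sc$mu, tMin = 3, sensitivity = 1e-3,
                       backgroundFraction = 0.3, rngSeed = 1, angles = ang,
                       noise = FALSE)
  bgTotal <- sum(sE@bgPerSlice) * dim(sE@counts)[1] * dim(sE@counts)[2]
  expect_equal(bgTotal / sum(sE@counts), 0.3, tolerance = 1e-9)
})

test_that("OSEM reconstructs a uniform disk quantitatively", {
  sc <- uniformCylinderScene(n = 64, nz = 3, spacingMm = 5, radiusMm = 120,
                             bqPerVoxel = 40)
  ang <- projectionAngles(48)
  sino <- simulateCounts(sc$activity, sc$mu, tMin = 3, sensitivity = 2e-3,
                         backgroundFraction = 0, rngSeed = 1, angles = ang,
                         noise = FALSE)
  img <- reconstructOSEM(sino, sc$mu, iterations = 20, postFilter = FALSE)
  truth <- 40 / (prod(sc$spacing) / 1000)
  rr <- outer((seq_len(64) - 32.5)^2, (seq_len(64) - 32.5)^2, "+")
  inner <- sc$disk & rr <= (90 / 5)^2
  expect_equal(mean(voxelData(img)[, , 2][inner]), truth,
               tolerance = 0.02)
  ## all-zero sinogram -> all-zero image
  sino0 <- sino; sino0@counts[] <- 0; sino0@bgPerSlice[] <- 0
  expect_true(all(voxelData(reconstructOSEM(sino0, sc$mu)) == 0))
  ## subsets must divide the angle count
  expect_error(reconstructOSEM(sino, sc$mu, subsets = 7), "divide")
})

test_that("a point source reconstructs at the source voxel", {
  sp <- c(4, 4, 4)
  act <- array(0, c(48, 48, 1)); act[30, 21, 1] <- 1000
  am <- methods::new("ActivityMap", data = act, spacing = sp,
                     injectedMBq = 1, uptakeMin = 0, decayApplied = FALSE)
  mu <- methods::new("MuMap", data = array(0, dim(act)), spacing = sp)
  sino <- simulateCounts(am, mu, tMin = 3, sensitivity = 1, rngSeed = 1,
                         backgroundFraction = 0, angles = projectionAngles(48),
                         noise = FALSE)
  img <- reconstructOSEM(sino, mu, iterations = 10, postFilter = FALSE)
  expect_identical(which.max(voxelData(img)),
                   which.max(act))
})

test_that("OSEM output is non-negative and positivity-preserving", {
  sc <- uniformCylinderScene(n = 48, nz = 2, spacingMm = 6)
  sino <- simulateCounts(sc$activity, sc$mu, tMin = 3, sensitivity = 1e-3,
                         backgroundFraction = 0.3, rngSeed = 4,
                         angles = projectionAngles(32))
  img <- reconstructOSEM(sino, sc$mu)
  expect_true(all(voxelData(img) >= 0))
})

test_that("the exact distance transform matches the brute-force oracle", {
  set.seed(7)
  m <- array(runif(15 * 12 * 9) > 0.6, c(15, 12, 9))
  spc <- c(2.73, 2.73, 2.79)
  d <- distanceToOutside(m, spc)
  idx <- which(m, arr.ind = TRUE, useNames = FALSE)
  out <- which(!m, arr.ind = TRUE, useNames = FALSE)
  bf <- PEThabitus:::minDistanceMm(idx, out, spc)
  expect_equal(d[m], bf, tolerance = 1e-9)
})

test_that("Gaussian post-filter preserves the mean and smooths", {
  set.seed(3)
  v <- array(rnorm(30 * 30 * 8, 100, 10), c(30, 30, 8))
  f <- PEThabitus:::gaussianFilter3d(v, c(5.5, 5.5, 4), c(3, 3, 3))
  expect_equal(mean(f), mean(v), tolerance = 0.01)
  expect_lt(sd(as.vector(f)), sd(as.vector(v)))
})
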