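## Spherical-growth tumour model: printed volumes, determinism, transfer.

## brute-force oracle: the voxel count minimising |n * V_vox - target|
bestVoxelCount <- function(targetMl, vvoxMl) {
  cand <- 0:ceiling(targetMl / vvoxMl + 2)
  cand[which.min(abs(cand * vvoxMl - targetMl))]
}

test_that("growth realises the eight printed volumes on the default grid", {
  spacing <- c(2.73, 2.73, 2.79)
  vvox <- prod(spacing) / 1000
  liver <- ellipsoidMask(c(60, 60, 60), spacing, c(70, 60, 65))
  seed <- c(30L, 30L, 30L)
  counts <- vapply(tumourTargetVolumesMl(), function(v)
    nrow(growTumour(liver, spacing, seed, v)), integer(1))
  oracle <- vapply(tumourTargetVolumesMl(), bestVoxelCount, numeric(1),
                   vvoxMl = vvox)
  expect_identical(counts, as.integer(oracle))
  expect_identical(counts, c(7L, 19L, 33L, 81L, 123L, 179L, 257L, 389L))
  ## realised within half a voxel of target
  expect_true(all(abs(counts * vvox - tumourTargetVolumesMl()) <= vvox / 2))
})

test_that("growth produces a ball: included voxels are nearest", {
  spacing <- c(1, 1, 1)
  liver <- array(TRUE, c(20, 20, 20))
  seed <- c(10L, 10L, 10L)
  mask <- growTumour(liver, spacing, seed, 0.268)
  expect_identical(nrow(mask), 268L)
  ## exhaustive distance-sort oracle
  all <- which(liver, arr.ind = TRUE, useNames = FALSE)
  d <- sqrt(rowSums(sweep(all, 2, seed, "-")^2))
  inSel <- paste(mask[, 1], mask[, 2], mask[, 3])
  sel <- paste(all[, 1], all[, 2], all[, 3]) %in% inSel
  expect_lte(max(d[sel]), min(d[!sel]) + 1e-9)
})

test_that("growth edge cases", {
  spacing <- c(2, 2, 2)
  liver <- array(TRUE, c(9, 9, 9))
  vvox <- prod(spacing) / 1000
  ## target of exactly one voxel volume -> the seed voxel
  m <- growTumour(liver, spacing, c(5L, 5L, 5L), vvox)
  expect_identical(m, matrix(c(5L, 5L, 5L), 1))
  ## below half a voxel -> error
  expect_error(growTumour(liver, spacing, c(5L, 5L, 5L), vvox / 4),
               "half a voxel")
  ## monotone growth: larger target is a superset
  m1 <- growTumour(liver, spacing, c(5L, 5L, 5L), 0.1)
  m2 <- growTumour(liver, spacing, c(5L, 5L, 5L), 0.3)
  k1 <- paste(m1[, 1], m1[, 2], m1[, 3])
  k2 <- paste(m2[, 1], m2[, 2], m2[, 3])
  expect_true(all(k1 %in% k2))
})

test_that("seed placement respects constraints and is deterministic", {
  spacing <- c(3, 3, 3)
  liver <- ellipsoidMask(c(50, 50, 50), spacing, c(65, 55, 60))
  s1 <- placeSeeds(liver, spacing, n = 8, minSeparationMm = 15,
                   marginMm = 10, rngSeed = 11)
  expect_identical(nrow(s1$seeds), 8L)
  expect_true(all(liver[s1$seeds]))
  pos <- sweep(s1$seeds - 0.5, 2, spacing, "*")
  dd <- as.matrix(dist(pos)); diag(dd) <- Inf
  expect_gte(min(dd), 15)
  s2 <- placeSeeds(liver, spacing, n = 8, minSeparationMm = 15,
                   marginMm = 10, rngSeed = 11)
  expect_identical(s1, s2)
  expect_false(identical(
    s1$seeds,
    placeSeeds(liver, spacing, 8, 15, 10, rngSeed = 12)$seeds))
})

test_that("single-voxel liver with zero margin places the seed there", {
  liver <- array(FALSE, c(5, 5, 5)); liver[3, 3, 3] <- TRUE
  s <- placeSeeds(liver, c(2, 2, 2), n = 1, minSeparationMm = 0,
                  marginMm = 0, rngSeed = 1)
  expect_identical(s$seeds, matrix(c(3L, 3L, 3L), 1))
})

test_that("unsatisfiable constraints report the achievable count", {
  liver <- array(FALSE, c(8, 8, 8)); liver[3:5, 3:5, 3:5] <- TRUE
  expect_error(placeSeeds(liver, c(2, 2, 2), n = 8, minSeparationMm = 50,
                          marginMm = 0, rngSeed = 1),
               "placed 1 of 8")
})

test_that("seed transfer preserves relative position", {
  spacing <- c(2, 2, 2)
  src <- array(FALSE, c(40, 40, 40)); src[5:20, 5:20, 5:20] <- TRUE
  s <- placeSeeds(src, spacing, n = 4, minSeparationMm = 6, marginMm = 2,
                  rngSeed = 3)
  ## identical livers -> identical voxels
  t1 <- transferSeeds(s$frac, src, spacing)
  expect_identical(t1$seeds, s$seeds)
  ## target scaled x2 about the corner: offsets scale x2 within one voxel
  tgt <- array(FALSE, c(40, 40, 40)); tgt[5:35, 5:35, 5:35] <- TRUE
  t2 <- transferSeeds(s$frac, tgt, spacing)
  offSrc <- sweep(s$seeds, 2, c(5, 5, 5), "-")
  offTgt <- sweep(t2$seeds, 2, c(5, 5, 5), "-")
  expect_true(all(abs(offTgt - 2 * offSrc) <= 2.01))
  ## centre fraction snaps inside the target liver
  t3 <- transferSeeds(matrix(0.5, 1, 3), tgt, spacing)
  expect_true(tgt[t3$seeds])
})

test_that("a full tumour set is disjoint, in-liver, and volume-accurate", {
  spacing <- c(3, 3, 3)
  liver <- ellipsoidMask(c(50, 50, 50), spacing, c(65, 55, 60))
  ts <- buildTumourSet(liver, spacing, rngSeed = 5)
  vvox <- prod(spacing) / 1000
  lab <- tumourLabelVolume(ts)
  ## disjoint: labels assigned once (sum of mask sizes == labelled voxels)
  expect_identical(sum(lab > 0L),
                   sum(vapply(ts@masks, nrow, integer(1))))
  expect_true(all(liver[lab > 0L]))
  expect_lte(abs(sum(ts@realisedMl) - sum(ts@targetsMl)),
             8 * vvox / 2)
  ## stamping overwrites liver codes with the tumour code
  ph <- boxPhantom(dim = c(50, 50, 50), spacing = spacing, code = 3L)
  ph2 <- addTumours(ph, ts)
  expect_identical(sum(voxelData(ph2) == structureCode("tumours")),
                   sum(lab > 0L))
})
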