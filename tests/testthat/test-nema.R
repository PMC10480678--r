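test_that("the NEMA fixture carries the 4:1 concentrations", {
  fx <- nemaFixture(spacing = c(4, 4, 4))
  expect_equal(fx$sphereConcKBqMl / fx$bgConcKBqMl, 41.0 / 10.3)
  expect_identical(round(fx$sphereConcKBqMl / fx$bgConcKBqMl), 4)
  expect_length(fx$sphereMasks, 6L)
  ## painted voxel activity matches concentration * voxel volume
  vvoxMl <- prod(fx$spacing) / 1000
  sph <- fx$sphereMasks[["37"]]
  expect_equal(fx$activity@data[sph][1], 41.0 * 1000 * vvoxMl)
})

test_that("exactly 60 background ROIs per diameter, pairwise disjoint", {
  fx <- nemaFixture(spacing = c(4, 4, 4))
  for (dn in c(37, 10)) {
    rois <- nemaBackgroundRois(fx, dn)
    expect_length(rois, 60L)
    ## 12 ROIs per slice across 5 slices
    slices <- vapply(rois, function(m) m[1, 3], numeric(1))
    expect_identical(length(unique(slices)), 5L)
    ## in-plane disjointness on the central slice
    onCentral <- rois[slices == fx$centralSlice]
    keys <- lapply(onCentral, function(m) paste(m[, 1], m[, 2]))
    expect_identical(anyDuplicated(unlist(keys)), 0L)
  }
})

test_that("a too-small fixture cannot host 37 mm background ROIs", {
  fx <- nemaFixture(spacing = c(4, 4, 4), interiorMm = c(70, 55))
  expect_error(nemaBackgroundRois(fx, 37), "ROI|fixture")
})

test_that("NEMA metrics recover known statistics of a synthetic image", {
  fx <- nemaFixture(spacing = c(4, 4, 4))
  rois <- lapply(fx$sphereDiameters, function(d) nemaBackgroundRois(fx, d))
  names(rois) <- as.character(fx$sphereDiameters)
  snrs <- cnrs <- matrix(NA_real_, 10, 6)
  for (k in 1:10) {
    img <- array(rnorm(prod(fx$dim), 100, 10), fx$dim)
    for (m in fx$sphereMasks) img[m] <- 400
    res <- nemaMetrics(img, fx$sphereMasks, rois)
    snrs[k, ] <- res@table$snr
    cnrs[k, ] <- res@table$cnr
    expect_identical(res@nBackgroundRois, 60L)
  }
  ## voxelwise N(100, 10) background, spheres at 400: SNR ~ 10, CNR ~ 30
  expect_equal(colMeans(snrs), rep(10, 6), tolerance = 0.05)
  expect_equal(colMeans(cnrs), rep(30, 6), tolerance = 0.05)
})

test_that("degenerate (constant) background raises an error", {
  fx <- nemaFixture(spacing = c(4, 4, 4))
  rois <- list("37" = nemaBackgroundRois(fx, 37))
  img <- array(7, fx$dim)
  img[fx$sphereMasks[["37"]]] <- 28
  expect_error(nemaMetrics(img, fx$sphereMasks["37"], rois),
               "degenerate background")
})

test_that("equal sphere and background means give zero CNR", {
  fx <- nemaFixture(spacing = c(4, 4, 4))
  rois <- list("37" = nemaBackgroundRois(fx, 37))
  set.seed(5)
  img <- array(rnorm(prod(fx$dim), 100, 10), fx$dim)
  img[fx$sphereMasks[["37"]]] <- 100
  res <- nemaMetrics(img, fx$sphereMasks["37"], rois)
  expect_lt(abs(res@table$cnr), 0.5)
})
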