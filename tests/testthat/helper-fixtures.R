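## Shared fixtures, built in code at test time.

## published cohort habitus (heights m, weights kg) and reported metrics
publishedCohort <- data.frame(
  phantom = paste0("P", 1:8),
  height = c(1.73, 1.74, 1.65, 1.79, 1.82, 1.75, 1.53, 1.79),
  weight = c(56, 68, 69, 89, 99, 100, 86, 120),
  bmi_printed = c(19, 23, 25, 28, 30, 33, 37, 38),
  circ_printed = c(72, 84, 97, 115, 113, 114, 117, 138),
  bsa_printed = c(1.67, 1.81, 1.76, 2.08, 2.20, 2.15, 1.83, 2.36)
)

## published per-phantom administered activities (MBq)
publishedActivities <- data.frame(
  phantom = paste0("P", 1:8),
  protocol_i = rep(100, 8),
  protocol_ii = c(112, 136, 138, 177, 198, 200, 172, 240),
  protocol_iii = c(81, 125, 129, 230, 297, 302, 215, 462)
)

## a hand-built phantom: an nx*ny*nz box of one structure code
boxPhantom <- function(dim = c(10, 10, 10), spacing = c(10, 10, 10),
                       code = 1L, heightM = dim[3] * spacing[3] / 1000) {
  methods::new("CodePhantom",
               codes = array(as.integer(code), dim), spacing = spacing,
               heightM = heightM, imagedRange = as.integer(c(1, dim[3])),
               name = "box", densityScale = 1, softTissueCode = 1L)
}

## a cylinder-body phantom (soft tissue only) with given radius [mm]
cylinderPhantom <- function(radiusMm = 100, spacing = c(2, 2, 4),
                            nz = 4, marginVox = 4) {
  n <- 2L * ceiling(radiusMm / spacing[1]) + 2L * marginVox
  xs <- (seq_len(n) - 0.5 - n / 2) * spacing[1]
  ys <- (seq_len(n) - 0.5 - n / 2) * spacing[2]
  disk <- outer(xs^2, ys^2, "+") <= radiusMm^2
  codes <- array(0L, c(n, n, nz))
  codes[, , seq_len(nz)][rep(disk, nz)] <- 1L
  methods::new("CodePhantom", codes = codes, spacing = spacing,
               heightM = nz * spacing[3] / 1000,
               imagedRange = as.integer(c(1, nz)), name = "cyl",
               densityScale = 1, softTissueCode = 1L)
}

## an ellipsoidal liver mask in a free-standing grid
ellipsoidMask <- function(dim, spacing, semiMm, centreIdx = dim / 2) {
  xs <- (seq_len(dim[1]) - centreIdx[1]) * spacing[1]
  ys <- (seq_len(dim[2]) - centreIdx[2]) * spacing[2]
  zs <- (seq_len(dim[3]) - centreIdx[3]) * spacing[3]
  outer(outer((xs / semiMm[1])^2, (ys / semiMm[2])^2, "+"),
        (zs / semiMm[3])^2, "+") <= 1
}

## a tiny water-cylinder activity/attenuation pair for simulator tests
uniformCylinderScene <- function(n = 96, nz = 8, spacingMm = 4,
                                 radiusMm = 150, bqPerVoxel = 50) {
  sp <- rep(spacingMm, 3)
  xs <- (seq_len(n) - 0.5 - n / 2) * spacingMm
  disk <- outer(xs^2, xs^2, "+") <= radiusMm^2
  act <- array(0, c(n, n, nz))
  act[, , seq_len(nz)][rep(disk, nz)] <- bqPerVoxel
  list(
    activity = methods::new("ActivityMap", data = act, spacing = sp,
                            injectedMBq = 1, uptakeMin = 0,
                            decayApplied = FALSE),
    mu = methods::new("MuMap", data = (act > 0) * 0.0096, spacing = sp),
    disk = disk, spacing = sp
  )
}

## small experiment configuration for fast end-to-end tests
miniConfig <- function(...) {
  ## coarse-grid fixture: the VOI holds few voxels, so the calibration
  ## tolerance is matched to the coarser median-SNR granularity
  experimentConfig(heights = c(1.60, 1.70, 1.80),
                   weights = c(60, 80, 100),
                   spacing = c(6, 6, 6), nAngles = 32L, subsets = 16L,
                   nReplicates = 1L, calibrationTol = 1.0, ...)
}
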