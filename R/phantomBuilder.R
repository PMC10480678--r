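## Synthetic voxel code-image phantoms across a habitus range.
##
## Anatomy model: torso = elliptical cylinder; legs = two circular
## cylinders; head = ellipsoid on a cylindrical neck; no arms (mirroring an
## arms-above-head acquisition). Organs are ellipsoids realised as
## nearest-n-voxel regions so that requested volumes are hit to within half
## a voxel. Only the relative geometry matters to the noise physics: organ
## volumes grow with weight, and the torso cross-section grows so that the
## voxel mass matches the requested weight.

## axial landmarks as fractions of body height
.Z_HIP <- 0.52
.Z_SHOULDER <- 0.82
.Z_NECK_TOP <- 0.86
## imaged axial range of a whole-body acquisition: mid-thigh to forehead
.Z_IMAGED <- c(0.40, 0.94)

## reference organ volumes [mL] at 70 kg, scaled linearly with weight
.ORGAN_VOLUMES_70KG <- c(liver = 1600, spleen = 180, kidney_l = 150,
                         kidney_r = 150, pancreas = 100, stomach_wall = 150,
                         bladder_contents = 160, lung_l = 1800, lung_r = 1800)

#' Build a geometric phantom specification for a given habitus
#'
#' Derives torso/leg/head dimensions and organ placements for a body of
#' the requested height and weight.  Transverse body dimensions are scaled
#' so that the voxelised mass approximates the requested weight; organ
#' volumes scale linearly with weight.
#'
#' @param heightM body height in m.
#' @param weightKg target body weight in kg.
#' @param spacing voxel spacing in mm (x, y, z).
#' @param name phantom identifier.
#' @param grid integer(2) in-plane grid size; `NULL` chooses the smallest
#'   even grid holding the torso with a margin.
#' @param organs logical; include the organ set (FALSE gives a soft-tissue
#'   body only).
#' @param forceWeightKg if not `NULL`, soft-tissue density is scaled
#'   uniformly at build time so the measured voxel weight equals this
#'   value exactly (defaults to `weightKg`; use `NA` to disable).
#' @return a named list understood by [buildPhantom()].
#' @export
#' @examples
#' spec <- phantomSpec(1.73, 56, spacing = c(8, 8, 8), name = "P1")
#' range(spec$torso$z)
phantomSpec <- function(heightM, weightKg, spacing = c(2.73, 2.73, 2.79),
                        name = "phantom", grid = NULL, organs = TRUE,
                        forceWeightKg = weightKg) {
  stopifnot(heightM > 0, weightKg > 0, all(spacing > 0))
  H <- heightM * 1000
  hs <- heightM / 1.75
  hipZ <- .Z_HIP * H
  shoulderZ <- .Z_SHOULDER * H
  neckTopZ <- .Z_NECK_TOP * H
  torsoL <- shoulderZ - hipZ

  ## reference transverse dimensions at this height, then a common
  ## transverse scale u chosen so body volume ~ weight at density ~1 g/mL
  torsoA0 <- 140 * hs; torsoB0 <- 105 * hs; legR0 <- 65 * hs
  headA <- 75 * hs; headB <- 90 * hs
  headC <- (H - neckTopZ) / 2
  neckR <- 55 * hs
  vTorso0 <- pi * torsoA0 * torsoB0 * torsoL
  vLegs0 <- 2 * pi * legR0^2 * hipZ
  vHeadNeck <- 4 / 3 * pi * headA * headB * headC +
    pi * neckR^2 * (neckTopZ - shoulderZ)
  vLungMl <- sum(.ORGAN_VOLUMES_70KG[c("lung_l", "lung_r")]) * weightKg / 70
  ## lungs (density 0.30) displace soft tissue: compensate the mass deficit
  targetMm3 <- weightKg * 1e6 + 0.70 * vLungMl * 1e3 - vHeadNeck
  u2 <- targetMm3 / (vTorso0 + vLegs0)
  if (u2 <= 0.01)
    stop(sprintf("infeasible habitus: weight %.1f kg at height %.2f m",
                 weightKg, heightM))
  u <- sqrt(u2)
  a <- torsoA0 * u; b <- torsoB0 * u; legR <- legR0 * u

  if (is.null(grid)) {
    nx <- 2L * ceiling((a + 6 * spacing[1]) / spacing[1])
    ny <- 2L * ceiling((b + 6 * spacing[2]) / spacing[2])
    grid <- c(max(nx, ny), max(nx, ny))
  }
  cx <- grid[1] * spacing[1] / 2
  cy <- grid[2] * spacing[2] / 2
  if (2 * a > grid[1] * spacing[1] - 2 * spacing[1] ||
      2 * b > grid[2] * spacing[2] - 2 * spacing[2])
    stop(sprintf("infeasible habitus: torso %.0f x %.0f mm exceeds the grid",
                 2 * a, 2 * b))

  vol <- .ORGAN_VOLUMES_70KG * weightKg / 70
  zt <- function(f) hipZ + f * torsoL   # fraction of torso length -> z [mm]
  organList <- if (!organs) list() else list(
    liver = list(code = .CODES[["liver"]], volumeMl = vol[["liver"]],
                 centre = c(cx + 0.34 * a, cy - 0.05 * b, zt(0.64)),
                 ratios = c(1.6, 1.2, 1.0)),
    spleen = list(code = .CODES[["spleen"]], volumeMl = vol[["spleen"]],
                  centre = c(cx - 0.58 * a, cy + 0.22 * b, zt(0.64)),
                  ratios = c(1.3, 1.0, 1.0)),
    kidney_l = list(code = .CODES[["kidneys"]], volumeMl = vol[["kidney_l"]],
                    centre = c(cx - 0.36 * a, cy + 0.44 * b, zt(0.36)),
                    ratios = c(1.0, 1.0, 1.5)),
    kidney_r = list(code = .CODES[["kidneys"]], volumeMl = vol[["kidney_r"]],
                    centre = c(cx + 0.36 * a, cy + 0.44 * b, zt(0.36)),
                    ratios = c(1.0, 1.0, 1.5)),
    pancreas = list(code = .CODES[["pancreas"]], volumeMl = vol[["pancreas"]],
                    centre = c(cx - 0.12 * a, cy - 0.02 * b, zt(0.47)),
                    ratios = c(2.2, 1.0, 0.8)),
    stomach_wall = list(code = .CODES[["stomach_wall"]],
                        volumeMl = vol[["stomach_wall"]],
                        centre = c(cx - 0.38 * a, cy - 0.28 * b, zt(0.57)),
                        ratios = c(1.3, 1.1, 1.2)),
    bladder_contents = list(code = .CODES[["bladder_contents"]],
                            volumeMl = vol[["bladder_contents"]],
                            centre = c(cx, cy - 0.15 * b, zt(0.07)),
                            ratios = c(1.2, 1.0, 1.0)),
    lung_l = list(code = .CODES[["lungs"]], volumeMl = vol[["lung_l"]],
                  centre = c(cx - 0.40 * a, cy, zt(0.88)),
                  ratios = c(0.9, 1.0, 1.7)),
    lung_r = list(code = .CODES[["lungs"]], volumeMl = vol[["lung_r"]],
                  centre = c(cx + 0.40 * a, cy, zt(0.88)),
                  ratios = c(0.9, 1.0, 1.7))
  )

  list(name = name, heightM = heightM, spacing = spacing, grid = grid,
       torso = list(cx = cx, cy = cy, a = a, b = b, z = c(hipZ, shoulderZ)),
       legs = list(r = legR, sep = min(legR * 1.15, a / 2), z = c(0, hipZ)),
       head = list(a = min(headA, a), b = min(headB, b), c = headC,
                   cz = (neckTopZ + H) / 2, neckR = min(neckR, a / 2),
                   neckZ = c(shoulderZ, neckTopZ)),
       organs = organList,
       forceWeightKg = if (is.null(forceWeightKg) || is.na(forceWeightKg))
         NULL else forceWeightKg)
}

#' Build a voxel code-image phantom from a geometric specification
#'
#' Rasterises the body regions and realises each organ as the
#' `round(volume / voxel volume)` voxels nearest its centre under the
#' organ's ellipsoidal metric, restricted to unclaimed body voxels, so the
#' requested volume is met to within one voxel volume.  Deterministic for
#' a fixed spec.
#'
#' @param spec a specification from [phantomSpec()] (or a hand-built list
#'   with the same fields; `organs` may be an empty list for a
#'   soft-tissue-only scene).
#' @param table a [StructureTable-class] used for the forced-weight
#'   density calibration.
#' @return a [CodePhantom-class].
#' @export
#' @examples
#' ph <- buildPhantom(phantomSpec(1.7, 70, spacing = c(10, 10, 10)))
#' ph
buildPhantom <- function(spec, table = defaultStructureTable()) {
  sp <- spec$spacing
  nx <- spec$grid[1]; ny <- spec$grid[2]
  H <- spec$heightM * 1000
  nz <- ceiling(H / sp[3])
  xs <- (seq_len(nx) - 0.5) * sp[1]
  ys <- (seq_len(ny) - 0.5) * sp[2]
  zs <- (seq_len(nz) - 0.5) * sp[3]

  codes <- array(0L, c(nx, ny, nz))
  soft <- .CODES[["soft_tissue"]]

  ## torso: one elliptical cross-section reused over its z-range
  to <- spec$torso
  ell <- outer(((xs - to$cx) / to$a)^2, ((ys - to$cy) / to$b)^2, "+") <= 1
  zSel <- which(zs >= to$z[1] & zs < to$z[2])
  codes[, , zSel][rep(ell, length(zSel))] <- soft

  if (!is.null(spec$legs)) {
    lg <- spec$legs
    leg2d <- (outer((xs - (to$cx - lg$sep))^2, (ys - to$cy)^2, "+") <= lg$r^2) |
             (outer((xs - (to$cx + lg$sep))^2, (ys - to$cy)^2, "+") <= lg$r^2)
    zSel <- which(zs >= lg$z[1] & zs < lg$z[2])
    codes[, , zSel][rep(leg2d, length(zSel))] <- soft
  }

  if (!is.null(spec$head)) {
    hd <- spec$head
    zSel <- which(zs >= hd$neckZ[1] & zs < hd$neckZ[2])
    neck2d <- outer((xs - to$cx)^2, (ys - to$cy)^2, "+") <= hd$neckR^2
    codes[, , zSel][rep(neck2d, length(zSel))] <- soft
    zSel <- which(abs(zs - hd$cz) <= hd$c)
    for (k in zSel) {
      f <- 1 - ((zs[k] - hd$cz) / hd$c)^2
      m <- outer(((xs - to$cx) / hd$a)^2, ((ys - to$cy) / hd$b)^2, "+") <= f
      slice <- codes[, , k]
      slice[m] <- soft
      codes[, , k] <- slice
    }
  }

  ## organs: nearest-n voxels under the ellipsoidal metric
  vvox <- prod(sp)
  for (nm in names(spec$organs)) {
    og <- spec$organs[[nm]]
    n <- round(og$volumeMl * 1000 / vvox)
    if (n < 1)
      stop(sprintf("organ '%s': volume below one voxel", nm))
    ## nominal ellipsoid semi-axes from volume and shape ratios
    s <- (og$volumeMl * 1000 * 3 / (4 * pi) / prod(og$ratios))^(1 / 3)
    semi <- og$ratios * s
    reach <- 1.6
    ix <- which(abs(xs - og$centre[1]) <= semi[1] * reach)
    iy <- which(abs(ys - og$centre[2]) <= semi[2] * reach)
    iz <- which(abs(zs - og$centre[3]) <= semi[3] * reach)
    if (!length(ix) || !length(iy) || !length(iz))
      stop(sprintf("organ '%s' placed outside the grid", nm))
    sub <- codes[ix, iy, iz, drop = FALSE]
    free <- sub == soft
    if (!any(free))
      stop(sprintf("organ '%s' placed outside the torso", nm))
    m2 <- outer(outer(((xs[ix] - og$centre[1]) / semi[1])^2,
                      ((ys[iy] - og$centre[2]) / semi[2])^2, "+"),
                ((zs[iz] - og$centre[3]) / semi[3])^2, "+")
    cidx <- which(free)
    if (length(cidx) < n)
      stop(sprintf("organ '%s' does not fit inside the torso", nm))
    ar <- arrayInd(cidx, dim(sub))
    ## deterministic tie-break: metric, then z, y, x
    ord <- order(m2[cidx], ar[, 3], ar[, 2], ar[, 1])
    take <- cidx[ord[seq_len(n)]]
    if (max(m2[take]) > reach^2)
      stop(sprintf("organ '%s' does not fit inside the torso", nm))
    ## a mandatory organ whose nominal ellipsoid is substantially claimed
    ## by another organ indicates overlapping placements (adjacent organs
    ## may touch; more than a quarter of the volume counts as overlap)
    claimed <- sub != soft & sub != 0L
    nomInside <- m2 <= 1
    if (sum(claimed & nomInside) > 0.25 * sum(nomInside))
      stop(sprintf("organ '%s' overlaps a previously placed organ", nm))
    sub[take] <- og$code
    codes[ix, iy, iz] <- sub
  }

  if (!any(codes > 0L)) stop("empty body mask")

  imaged <- as.integer(c(max(1, ceiling(.Z_IMAGED[1] * H / sp[3])),
                         min(nz, ceiling(.Z_IMAGED[2] * H / sp[3]))))
  ph <- methods::new("CodePhantom", codes = codes, spacing = sp,
                     heightM = spec$heightM, imagedRange = imaged,
                     name = spec$name, densityScale = 1,
                     softTissueCode = as.integer(soft))

  if (!is.null(spec$forceWeightKg)) {
    dens <- structureDensity(table, codes)
    massKg <- sum(dens) * (vvox / 1000) / 1000  # g/cm3 * mL -> g -> kg
    softMassKg <- sum(dens[codes == soft]) * (vvox / 1000) / 1000
    if (softMassKg <= 0) stop("cannot force weight: no soft tissue present")
    scale <- 1 + (spec$forceWeightKg - massKg) / softMassKg
    if (scale <= 0)
      stop("cannot force weight: target below non-soft-tissue mass")
    ph@densityScale <- scale
  }
  ph
}

## published habitus defaults for the eight-phantom cohort
.COHORT_HEIGHTS <- c(1.73, 1.74, 1.65, 1.79, 1.82, 1.75, 1.53, 1.79)
.COHORT_WEIGHTS <- c(56, 68, 69, 89, 99, 100, 86, 120)

#' Generate a cohort of phantoms spanning a habitus range
#'
#' The default cohort reproduces the eight published height/weight pairs,
#' whose BMIs span 19-38 kg/m^2 in non-decreasing order.  When explicit
#' weights are not supplied, weights are derived from a BMI range at
#' interpolated heights.
#'
#' @param n number of phantoms (>= 2).
#' @param heights,weights numeric vectors of length `n`; defaults mirror
#'   the published cohort when `n = 8`.
#' @param bmiRange BMI range used to derive weights when `weights` is
#'   `NULL`.
#' @param spacing voxel spacing in mm.
#' @param grid in-plane grid; `NULL` picks one grid fitting the largest
#'   phantom, shared by the cohort.
#' @param organs include the organ set.
#' @param table a [StructureTable-class].
#' @return named list of [CodePhantom-class] objects (P1, P2, ...).
#' @export
#' @examples
#' coh <- generateCohort(n = 2, heights = c(1.7, 1.7), weights = c(60, 90),
#'                       spacing = c(12, 12, 12), organs = FALSE)
#' names(coh)
generateCohort <- function(n = 8, heights = NULL, weights = NULL,
                           bmiRange = c(19, 38),
                           spacing = c(2.73, 2.73, 2.79), grid = NULL,
                           organs = TRUE, table = defaultStructureTable()) {
  if (n < 2) stop("cohort needs at least 2 phantoms")
  publishedCohort <- is.null(heights) && is.null(weights) && n == 8
  if (is.null(heights))
    heights <- if (n == 8) .COHORT_HEIGHTS else
      seq(1.65, 1.80, length.out = n)
  if (is.null(weights)) {
    if (publishedCohort) {
      weights <- .COHORT_WEIGHTS
    } else {
      if (any(bmiRange <= 0) || bmiRange[2] < bmiRange[1])
        stop("invalid BMI range")
      bmis <- seq(bmiRange[1], bmiRange[2], length.out = n)
      weights <- bmis * heights^2
    }
  }
  stopifnot(length(heights) == n, length(weights) == n)
  specs <- lapply(seq_len(n), function(i)
    phantomSpec(heights[i], weights[i], spacing = spacing,
                name = sprintf("P%d", i), grid = grid, organs = organs))
  if (is.null(grid)) {
    gmax <- max(vapply(specs, function(s) s$grid[1], numeric(1)))
    specs <- lapply(seq_len(n), function(i)
      phantomSpec(heights[i], weights[i], spacing = spacing,
                  name = sprintf("P%d", i), grid = c(gmax, gmax),
                  organs = organs))
  }
  out <- lapply(specs, buildPhantom, table = table)
  names(out) <- vapply(out, phantomName, character(1))
  out
}
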