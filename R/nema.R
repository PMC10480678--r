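## NEMA-style image-quality fixture: six fillable spheres in a warm
## background, with the 60-ROI background analysis.

.NEMA_SPHERE_DIAMETERS <- c(37, 28, 22, 17, 13, 10)
.NEMA_RING_RADIUS_MM <- 57.2

#' Synthetic NEMA IQ fixture
#'
#' An elliptical-cylinder background compartment with six spheres
#' (diameters 37-10 mm) on a 57.2 mm ring in the central slice, filled at
#' 10.3 kBq/mL (background) and 41.0 kBq/mL (spheres) -- a
#' sphere-to-background ratio of approximately 4:1.  The interior is
#' slightly larger than the physical phantom so that a full complement of
#' twelve 37 mm background ROIs fits at the 15 mm edge margin.
#'
#' @param spacing voxel spacing in mm.
#' @param interiorMm semi-axes (a, b) of the background ellipse in mm.
#' @param lengthMm axial extent in mm.
#' @param bgConcKBqMl,sphereConcKBqMl activity concentrations in kBq/mL.
#' @return list with `activity` ([ActivityMap-class]), `mu`
#'   ([MuMap-class]), `sphereMasks` (in-plane ROI index matrices over each
#'   sphere, named by diameter), `sphereCentresMm`, `sphereDiameters`,
#'   `interiorMm`, `centreMm`, `centralSlice`, `spacing`, and the two
#'   concentrations.
#' @export
nemaFixture <- function(spacing = c(3, 3, 3), interiorMm = c(160, 130),
                        lengthMm = 96, bgConcKBqMl = 10.3,
                        sphereConcKBqMl = 41.0) {
  a <- interiorMm[1]; b <- interiorMm[2]
  nx <- 2L * ceiling((a + 3 * spacing[1]) / spacing[1])
  ny <- 2L * ceiling((b + 3 * spacing[2]) / spacing[2])
  nz <- ceiling(lengthMm / spacing[3])
  cx <- nx * spacing[1] / 2; cy <- ny * spacing[2] / 2
  kc <- as.integer(ceiling(nz / 2))
  xs <- (seq_len(nx) - 0.5) * spacing[1]
  ys <- (seq_len(ny) - 0.5) * spacing[2]

  conc <- array(0, c(nx, ny, nz))            # kBq/mL
  inEll <- outer(((xs - cx) / a)^2, ((ys - cy) / b)^2, "+") <= 1
  conc[, , seq_len(nz)][rep(inEll, nz)] <- bgConcKBqMl

  ang <- (seq_len(6) - 1) * pi / 3
  centres <- cbind(cx + .NEMA_RING_RADIUS_MM * cos(ang),
                   cy + .NEMA_RING_RADIUS_MM * sin(ang),
                   (kc - 0.5) * spacing[3])
  sphereMasks <- vector("list", 6)
  for (i in 1:6) {
    r <- .NEMA_SPHERE_DIAMETERS[i] / 2
    sph <- ballMask(c(nx, ny, nz), spacing,
                    c(round(centres[i, 1] / spacing[1] + 0.5),
                      round(centres[i, 2] / spacing[2] + 0.5), kc),
                    .NEMA_SPHERE_DIAMETERS[i])
    conc[sph] <- sphereConcKBqMl
    ## in-plane ROI over the sphere: central-slice disc of sphere diameter
    roi <- sph
    roi[, , -kc] <- FALSE
    sphereMasks[[i]] <- maskIndices(roi)
  }
  names(sphereMasks) <- as.character(.NEMA_SPHERE_DIAMETERS)

  vvoxMl <- prod(spacing) / 1000
  act <- methods::new("ActivityMap", data = conc * 1000 * vvoxMl,
                      spacing = spacing,
                      injectedMBq = sum(conc) * 1000 * vvoxMl / 1e6,
                      uptakeMin = 0, decayApplied = FALSE)
  mu <- methods::new("MuMap", data = (conc > 0) * .MU_WATER_511,
                     spacing = spacing)
  list(activity = act, mu = mu, sphereMasks = sphereMasks,
       sphereCentresMm = centres,
       sphereDiameters = .NEMA_SPHERE_DIAMETERS,
       interiorMm = interiorMm, centreMm = c(cx, cy), centralSlice = kc,
       spacing = spacing, bgConcKBqMl = bgConcKBqMl,
       sphereConcKBqMl = sphereConcKBqMl, dim = c(nx, ny, nz))
}

#' Background ROI template
#'
#' Twelve unit-circle directions; ROI centres are obtained by scaling the
#' template to the fixture's background ellipse after subtracting the
#' edge margin and the ROI radius.  Shipped as
#' `extdata/nema_roi_template.csv`.
#'
#' @return data.frame with columns `ux`, `uy`.
#' @export
nemaRoiTemplate <- function() {
  path <- system.file("extdata", "nema_roi_template.csv",
                      package = "PEThabitus", mustWork = TRUE)
  utils::read.csv(path)
}

#' Place the 60 NEMA background ROIs
#'
#' Twelve in-plane disc ROIs of the requested diameter are placed from the
#' fixed template on the central slice and replicated on the slices
#' closest to +-1 cm and +-2 cm (5 x 12 = 60 ROIs).  Placement fails if a
#' ROI would come within `edgeMarginMm` of the phantom edge, intersect a
#' sphere (with `sphereMarginMm` clearance), or overlap another ROI.
#'
#' @param fixture a fixture from [nemaFixture()].
#' @param diameterMm ROI diameter (one of the sphere diameters).
#' @param edgeMarginMm minimum distance from ROI edge to phantom edge.
#' @param sphereMarginMm minimum clearance between ROI and sphere
#'   surfaces.
#' @param template data.frame of unit directions (default
#'   [nemaRoiTemplate()]).
#' @return list of 60 ROI voxel-index matrices.
#' @export
nemaBackgroundRois <- function(fixture, diameterMm, edgeMarginMm = 15,
                               sphereMarginMm = 0,
                               template = nemaRoiTemplate()) {
  r <- diameterMm / 2
  a <- fixture$interiorMm[1] - edgeMarginMm - r
  b <- fixture$interiorMm[2] - edgeMarginMm - r
  if (a <= 0 || b <= 0)
    stop(sprintf("fixture too small for %g mm background ROIs", diameterMm))
  scale <- 0.97
  cx <- fixture$centreMm[1]; cy <- fixture$centreMm[2]
  centres <- cbind(cx + scale * a * template$ux,
                   cy + scale * b * template$uy)

  ## validity: inside the margin ellipse, clear of all spheres
  sc <- fixture$sphereCentresMm
  for (i in seq_len(nrow(centres))) {
    ex <- (centres[i, 1] - cx) / (fixture$interiorMm[1] - edgeMarginMm - r)
    ey <- (centres[i, 2] - cy) / (fixture$interiorMm[2] - edgeMarginMm - r)
    if (ex^2 + ey^2 > 1 + 1e-9)
      stop(sprintf("background ROI %d violates the %g mm edge margin",
                   i, edgeMarginMm))
    dSph <- sqrt((sc[, 1] - centres[i, 1])^2 + (sc[, 2] - centres[i, 2])^2)
    if (any(dSph < r + fixture$sphereDiameters / 2 + sphereMarginMm - 1e-9))
      stop(sprintf("background ROI %d intersects a sphere", i))
  }
  dd <- as.matrix(stats::dist(centres))
  diag(dd) <- Inf
  if (any(dd < 2 * r - 1e-9))
    stop("background ROIs overlap in-plane; cannot fit 12 ROIs")

  sp <- fixture$spacing
  kc <- fixture$centralSlice
  offs <- c(0, -20, -10, 10, 20)
  slices <- unique(pmin(pmax(kc + round(offs / sp[3]), 1L), fixture$dim[3]))
  if (length(slices) != 5L)
    stop("fixture too short for the +-2 cm background slices")

  xs <- (seq_len(fixture$dim[1]) - 0.5) * sp[1]
  ys <- (seq_len(fixture$dim[2]) - 0.5) * sp[2]
  rois <- vector("list", 12L * 5L)
  k <- 0L
  for (sl in slices) {
    for (i in seq_len(nrow(centres))) {
      disc <- outer((xs - centres[i, 1])^2, (ys - centres[i, 2])^2, "+") <= r^2
      ij <- which(disc, arr.ind = TRUE, useNames = FALSE)
      if (!nrow(ij)) stop("background ROI smaller than one voxel")
      k <- k + 1L
      rois[[k]] <- cbind(ij, sl)
    }
  }
  rois
}

#' NEMA sphere SNR and CNR
#'
#' For each sphere diameter i: `SNR_i = mean_B,i / sd_B,i` and
#' `CNR_i = (mean_S,i - mean_B,i) / sd_B,i`, where `mean_B,i` is the mean
#' of the 60 background-ROI means, `sd_B,i` the population SD over all
#' voxels pooled across the 60 ROIs, and `mean_S,i` the mean over the ROI
#' covering the sphere.
#'
#' @param image a [ReconImage-class] or numeric 3-D array.
#' @param sphereMasks named list of sphere ROI index matrices (as from
#'   [nemaFixture()]).
#' @param backgroundRois named list (by diameter) of 60-ROI lists from
#'   [nemaBackgroundRois()].
#' @return a [NemaResult-class].
#' @export
nemaMetrics <- function(image, sphereMasks, backgroundRois) {
  img <- if (methods::is(image, "ReconImage")) image@data else image
  stopifnot(all(names(sphereMasks) %in% names(backgroundRois)) ||
            length(backgroundRois) == length(sphereMasks))
  rows <- lapply(names(sphereMasks), function(dn) {
    rois <- backgroundRois[[dn]]
    if (length(rois) != 60L)
      stop(sprintf("expected 60 background ROIs for diameter %s, got %d",
                   dn, length(rois)))
    roiMeans <- vapply(rois, function(m) mean(img[m]), numeric(1))
    pooled <- unlist(lapply(rois, function(m) img[m]))
    xB <- mean(roiMeans)
    sB <- popSd(pooled)
    if (sB == 0) stop("degenerate background: zero standard deviation")
    xS <- mean(img[sphereMasks[[dn]]])
    data.frame(diameter_mm = as.numeric(dn), bg_mean = xB, bg_sd = sB,
               sphere_mean = xS, snr = xB / sB, cnr = (xS - xB) / sB)
  })
  methods::new("NemaResult", table = do.call(rbind, rows),
               nBackgroundRois = 60L)
}
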