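## Internal numerical helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so simulation helpers do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and a tag
#'
#' Deterministic integer mixing so that each (phantom, protocol, purpose)
#' combination gets its own reproducible random stream below 2^31.
#'
#' @param master integer master seed.
#' @param ... tags (strings or integers) identifying the consumer.
#' @return integer in `[0, 2^31)`.
#' @export
#' @examples
#' childSeed(1, "P3", "protocol_ii")
childSeed <- function(master, ...) {
  tags <- vapply(list(...), function(t) paste(format(t), collapse = "|"),
                 character(1))
  h <- as.double(master) %% 2147483647
  for (tag in tags) {
    for (v in utf8ToInt(paste0("#", tag))) {
      h <- (h * 69069 + v * 2654435761) %% 2147483647
    }
  }
  as.integer(h)
}

## population standard deviation (divisor N) -- the convention used by all
## SNR/CNR formulas in the package
popSd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

## Separable Gaussian filter on a 3-D array; FWHM given per axis in mm.
## Kernels are truncated at 3 sigma and renormalised; replicate padding.
gaussianFilter3d <- function(vol, fwhmMm, spacing) {
  stopifnot(length(fwhmMm) == 3L, length(spacing) == 3L)
  d <- dim(vol)
  kern <- lapply(1:3, function(ax) {
    sigma <- fwhmMm[ax] / (2 * sqrt(2 * log(2))) / spacing[ax]
    if (sigma < 1e-6) return(1)
    hw <- max(1L, ceiling(3 * sigma))
    k <- exp(-(seq(-hw, hw))^2 / (2 * sigma^2))
    k / sum(k)
  })
  array(cpp_gauss3d(as.double(vol), d[1], d[2], d[3],
                    kern[[1]], kern[[2]], kern[[3]]), d)
}

## Perimeter of the largest closed contour of a binary slice [mm].
## The mask is lightly smoothed before the 0.5-level contour is traced so
## the contour follows the underlying shape rather than the voxel staircase.
maskPerimeterMm <- function(mask, spacing2d, smooth = TRUE) {
  m <- matrix(as.numeric(mask), nrow = nrow(mask))
  if (!any(m > 0)) return(0)
  if (smooth) {
    k <- c(1, 2, 1) / 4
    m2 <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
    m <- k[1] * m2[1:nrow(m), , drop = FALSE] +
         k[2] * m2[2:(nrow(m) + 1), , drop = FALSE] +
         k[3] * m2[3:(nrow(m) + 2), , drop = FALSE]
    m2 <- cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
    m <- k[1] * m2[, 1:ncol(m), drop = FALSE] +
         k[2] * m2[, 2:(ncol(m) + 1), drop = FALSE] +
         k[3] * m2[, 3:(ncol(m) + 2), drop = FALSE]
  }
  ## zero-pad so bodies touching the grid edge still close their contour
  m <- rbind(0, cbind(0, m, 0), 0)
  xs <- seq_len(nrow(m)) * spacing2d[1]
  ys <- seq_len(ncol(m)) * spacing2d[2]
  cl <- grDevices::contourLines(xs, ys, m, levels = 0.5)
  if (!length(cl)) return(0)
  per <- vapply(cl, function(cc) {
    dx <- diff(c(cc$x, cc$x[1]))
    dy <- diff(c(cc$y, cc$y[1]))
    sum(sqrt(dx^2 + dy^2))
  }, numeric(1))
  max(per)
}

## Index matrix (n x 3) of TRUE voxels of a logical 3-D array
maskIndices <- function(mask) {
  which(mask, arr.ind = TRUE, useNames = FALSE)
}

## Physical coordinates (mm) of voxel centres for an index matrix
voxelCentresMm <- function(idx, spacing) {
  sweep(idx - 0.5, 2, spacing, "*")
}

## For each candidate voxel, the minimum physical distance to any obstacle
## voxel. Chunked brute force; obstacle and candidate given as index
## matrices. Returns a numeric vector parallel to candIdx rows.
minDistanceMm <- function(candIdx, obstIdx, spacing, chunk = 2048L) {
  if (nrow(obstIdx) == 0L)
    return(rep(Inf, nrow(candIdx)))
  pc <- voxelCentresMm(candIdx, spacing)
  po <- voxelCentresMm(obstIdx, spacing)
  out <- numeric(nrow(pc))
  for (start in seq(1L, nrow(pc), by = chunk)) {
    sel <- start:min(start + chunk - 1L, nrow(pc))
    d2 <- outer(rowSums(pc[sel, , drop = FALSE]^2), rowSums(po^2), "+") -
      2 * pc[sel, , drop = FALSE] %*% t(po)
    out[sel] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

## Logical mask of a ball of given diameter (mm) centred on a voxel index
ballMask <- function(dim, spacing, centreIdx, diameterMm) {
  r <- diameterMm / 2
  hw <- ceiling(r / spacing) + 1L
  lo <- pmax(centreIdx - hw, 1L)
  hi <- pmin(centreIdx + hw, dim)
  mask <- array(FALSE, dim)
  xs <- (lo[1]:hi[1] - centreIdx[1]) * spacing[1]
  ys <- (lo[2]:hi[2] - centreIdx[2]) * spacing[2]
  zs <- (lo[3]:hi[3] - centreIdx[3]) * spacing[3]
  d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- d2 <= r^2
  mask
}
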