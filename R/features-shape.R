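# Separable Gaussian smoothing of a 3D array, sigma given per axis in voxels.
# Zero-padded at the edges (background extension for masks).
gaussSmooth3D <- function(arr, sigmaVox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    out <- array(0, dim = d)
    for (j in seq(-r, r)) {
      w <- k[j + r + 1L]
      src <- seq_len(d[ax])
      keep <- src + j >= 1L & src + j <= d[ax]
      if (!any(keep)) next
      dst <- src[keep]
      from <- dst + j
      if (ax == 1L) out[dst, , ] <- out[dst, , ] + w * arr[from, , ]
      else if (ax == 2L) out[, dst, ] <- out[, dst, ] + w * arr[, from, ]
      else out[, , dst] <- out[, , dst] + w * arr[, , from]
    }
    arr <- out
  }
  arr
}

# Central-difference gradient magnitude with physical spacing; one-sided at
# the array edges is avoided by zero padding (consistent with smoothing).
gradMagnitude3D <- function(arr, spacing) {
  d <- dim(arr)
  shift <- function(a, ax, by) {
    out <- array(0, dim = d)
    src <- seq_len(d[ax])
    keep <- src + by >= 1L & src + by <= d[ax]
    dst <- src[keep]; from <- dst + by
    if (ax == 1L) out[dst, , ] <- a[from, , ]
    else if (ax == 2L) out[, dst, ] <- a[, from, ]
    else out[, , dst] <- a[, , from]
    out
  }
  gx <- (shift(arr, 1L, 1L) - shift(arr, 1L, -1L)) / (2 * spacing[1])
  gy <- (shift(arr, 2L, 1L) - shift(arr, 2L, -1L)) / (2 * spacing[2])
  gz <- (shift(arr, 3L, 1L) - shift(arr, 3L, -1L)) / (2 * spacing[3])
  sqrt(gx^2 + gy^2 + gz^2)
}

# Surface area (mm^2) of a binary mask: coarea estimate, integrating the
# gradient magnitude of the Gaussian-smoothed indicator over the grid.
maskSurfaceArea <- function(m, spacing) {
  sigmaMM <- 1.5 * max(spacing)
  sm <- gaussSmooth3D(array(as.numeric(m), dim = dim(m)), sigmaMM / spacing)
  sum(gradMagnitude3D(sm, spacing)) * prod(spacing)
}

# Foreground voxels with a background 6-neighbour (or on the grid edge).
surfaceVoxelCoords <- function(m, spacing) {
  d <- dim(m)
  idx <- which(m, arr.ind = TRUE)
  onSurf <- rep(FALSE, nrow(idx))
  for (k in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- idx
      nb[, k] <- nb[, k] + s
      out <- nb[, k] < 1L | nb[, k] > d[k]
      inb <- !out
      hasBg <- rep(FALSE, nrow(idx))
      hasBg[out] <- TRUE
      if (any(inb)) hasBg[inb] <- !m[nb[inb, , drop = FALSE]]
      onSurf <- onSurf | hasBg
    }
  }
  sweep(idx[onSurf, , drop = FALSE], 2L, spacing, `*`)
}

#' Shape features of a lesion mask
#'
#' The 11-feature shape catalog: mesh-free volume and surface area in
#' physical units, their ratio, three sphericity-type descriptors, the
#' maximum 3D diameter (largest distance between foreground voxel centres,
#' mm) and the three principal axis lengths from the second moments of the
#' voxel coordinates (4*sqrt(eigenvalue), mm).
#'
#' @param mask a nonempty \linkS4class{RegionMask}.
#' @return named numeric vector of length 11, names prefixed \code{SHAPE_}.
#' @export
shapeFeatures <- function(mask) {
  m <- voxels(mask)
  if (!any(m)) stop("empty mask")
  sp <- voxelSpacing(mask)
  nvox <- sum(m)
  V <- nvox * prod(sp)
  A <- maskSurfaceArea(m, sp)
  R <- (3 * V / (4 * pi))^(1 / 3)
  coords <- surfaceVoxelCoords(m, sp)
  maxDiam <- if (nrow(coords) > 1L) cpp_max_pair_dist(coords) else 0
  allCoords <- sweep(which(m, arr.ind = TRUE), 2L, sp, `*`)
  axes <- if (nvox > 1L) {
    ev <- sort(eigen(stats::cov(allCoords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    4 * sqrt(pmax(ev, 0))
  } else c(0, 0, 0)
  c(SHAPE_volume = V,
    SHAPE_surfaceArea = A,
    SHAPE_surfToVolRatio = A / V,
    SHAPE_sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    SHAPE_compactness1 = V / (sqrt(pi) * A^(3 / 2)),
    SHAPE_compactness2 = 36 * pi * V^2 / A^3,
    SHAPE_sphericalDisprop = A / (4 * pi * R^2),
    SHAPE_maxDiameter3D = maxDiam,
    SHAPE_majorAxis = axes[1],
    SHAPE_minorAxis = axes[2],
    SHAPE_leastAxis = axes[3])
}
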