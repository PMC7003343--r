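#' Discretize in-mask intensities into gray levels
#'
#' Equal-width binning of the in-mask intensities between the in-mask
#' minimum and maximum into \code{nLevels} bins. The maximum intensity maps
#' to level \code{nLevels}; a constant region maps wholly to level 1. This
#' min--max scheme makes all downstream matrix textures invariant to adding
#' a constant to the image.
#'
#' @param volume an \linkS4class{ImageVolume} (or plain 3D array).
#' @param mask a \linkS4class{RegionMask} with at least one foreground voxel.
#' @param nLevels number of gray levels (>= 2; default 32).
#' @return a \linkS4class{QuantizedRegion}.
#' @export
quantizeRegion <- function(volume, mask, nLevels = 32L) {
  v <- if (is(volume, "ImageVolume")) voxels(volume) else volume
  m <- voxels(mask)
  if (!identical(dim(v), dim(m)))
    stop(sprintf("mask dims (%s) do not match volume dims (%s)",
                 paste(dim(m), collapse = "x"),
                 paste(dim(v), collapse = "x")))
  if (!any(m)) stop("cannot quantize an empty mask")
  nLevels <- as.integer(nLevels)
  if (nLevels < 2L) stop("nLevels must be >= 2")
  x <- v[m]
  lo <- min(x); hi <- max(x)
  lev <- array(NA_integer_, dim = dim(v))
  if (hi == lo) {
    lev[m] <- 1L
  } else {
    w <- (hi - lo) / nLevels
    lev[m] <- pmin.int(as.integer(floor((x - lo) / w)) + 1L, nLevels)
  }
  new("QuantizedRegion", levels = lev, nLevels = nLevels,
      voxelCount = sum(m), spacing = voxelSpacing(mask))
}
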