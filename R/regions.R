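#' Peritumoral band mask
#'
#' Builds the band region centred on the lesion boundary: in-lesion voxels
#' whose Euclidean distance to the nearest background voxel is at most
#' \code{innerMM}, united with background voxels whose distance to the
#' nearest lesion voxel is at most \code{outerMM}. Distances use the
#' physical (anisotropic) voxel spacing; the defaults give the 10 mm band
#' (5 mm inner + 5 mm outer). If the band reaches the grid edge it is
#' truncated with a warning.
#'
#' @param lesion a nonempty lesion \linkS4class{RegionMask}.
#' @param innerMM inner half-width of the band in mm (default 5).
#' @param outerMM outer half-width in mm (default 5).
#' @return a \linkS4class{RegionMask} with \code{regionKind}
#'   \code{"peripheral_band"}.
#' @export
peripheralBandMask <- function(lesion, innerMM = 5, outerMM = 5) {
  m <- voxels(lesion)
  if (!any(m)) stop("empty lesion mask")
  if (innerMM < 0 || outerMM < 0 || innerMM + outerMM <= 0)
    stop("band widths must be non-negative with positive total width")
  sp <- voxelSpacing(lesion)
  d <- dim(m)
  # distance of inside voxels to nearest background voxel
  distToBg <- cpp_edt(!m, d, sp)
  # distance of outside voxels to nearest lesion voxel
  distToFg <- cpp_edt(m, d, sp)
  band <- (m & distToBg <= innerMM) | (!m & distToFg <= outerMM)
  # truncation check: does the outer reach extend beyond the grid?
  edge <- array(FALSE, dim = d)
  edge[c(1L, d[1]), , ] <- TRUE
  edge[, c(1L, d[2]), ] <- TRUE
  edge[, , c(1L, d[3])] <- TRUE
  if (any(band & edge))
    warning("peripheral band truncated at the grid edge")
  new("RegionMask", voxels = band, spacing = sp,
      regionKind = "peripheral_band")
}

#' Peripheral (band) texture features
#'
#' The 77 non-shape features (histogram + GLCM + GLRLM + GLZSM) computed in
#' the peritumoral band, quantized on the band's own intensity range.
#' Names carry the \code{Bndry_} prefix (e.g. \code{Bndry_GLCM_contrast}).
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param band the band \linkS4class{RegionMask} from
#'   \code{\link{peripheralBandMask}}.
#' @param nLevels gray levels for quantization.
#' @return named numeric vector of length 77.
#' @export
peripheralFeatures <- function(volume, band, nLevels = 32L) {
  checkCompanion(band, volume)
  if (!any(voxels(band))) stop("empty band region")
  f <- intensityFeatures(volume, band, nLevels)
  stats::setNames(f, paste0("Bndry_", names(f)))
}
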