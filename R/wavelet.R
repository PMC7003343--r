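waveletFilters <- function(basisName) {
  lo <- switch(basisName,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    stop("unknown wavelet basis: ", basisName))
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  list(L = lo, H = hi)
}

# Undecimated filtering along one axis with half-sample symmetric extension.
applyFilterAxis <- function(arr, h, ax) {
  d <- dim(arr)
  n <- d[ax]
  out <- array(0, dim = d)
  for (k in seq_along(h)) {
    idx <- seq_len(n) + (k - 1L)
    idx[idx > n] <- 2L * n + 1L - idx[idx > n]
    if (ax == 1L) out <- out + h[k] * arr[idx, , , drop = FALSE]
    else if (ax == 2L) out <- out + h[k] * arr[, idx, , drop = FALSE]
    else out <- out + h[k] * arr[, , idx, drop = FALSE]
  }
  out
}

#' Single-stage stationary 3D wavelet decomposition
#'
#' Separable application of the basis's low- (L) and high-pass (H) filters
#' along X, Y and Z in all eight combinations, undecimated (stationary)
#' with half-sample symmetric boundary extension. Subband label position 1
#' names the X filter, position 2 the Y filter, position 3 the Z filter.
#' Because no decimation occurs, every subband keeps the dims and spacing
#' of the input, so the original lesion mask applies to each subband.
#'
#' @param volume an \linkS4class{ImageVolume} with each dim >= 2.
#' @param basisName wavelet basis, \code{"haar"} (default) or \code{"db2"}.
#' @return a \linkS4class{SubbandSet}.
#' @export
waveletDecompose <- function(volume, basisName = "haar") {
  filt <- waveletFilters(basisName)
  v <- voxels(volume)
  if (any(dim(v) < 2L)) stop("volume dims must each be >= 2")
  alongX <- lapply(filt, function(h) applyFilterAxis(v, h, 1L))
  alongXY <- list()
  for (fx in c("L", "H"))
    for (fy in c("L", "H"))
      alongXY[[paste0(fx, fy)]] <- applyFilterAxis(alongX[[fx]], filt[[fy]], 2L)
  subbands <- list()
  for (lab in SUBBAND_LABELS) {
    xy <- substr(lab, 1L, 2L)
    fz <- substr(lab, 3L, 3L)
    subbands[[lab]] <- applyFilterAxis(alongXY[[xy]], filt[[fz]], 3L)
  }
  new("SubbandSet", subbands = subbands, basisName = basisName,
      spacing = voxelSpacing(volume))
}

#' Wavelet-transformed texture features
#'
#' For each of the eight stationary subbands, computes the 77 non-shape
#' features inside the original lesion mask, each subband quantized on its
#' own in-mask min--max range (subband value ranges differ by orders of
#' magnitude). Names are prefixed by the subband label, e.g.
#' \code{HHH_GLCM_correlation}; 8 x 77 = 616 features in total.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param lesion the lesion \linkS4class{RegionMask}.
#' @param nLevels gray levels for quantization.
#' @param basisName wavelet basis name.
#' @return named numeric vector of length 616.
#' @export
waveletFeatures <- function(volume, lesion, nLevels = 32L,
                            basisName = "haar") {
  checkCompanion(lesion, volume)
  if (!any(voxels(lesion))) stop("empty lesion mask")
  sb <- waveletDecompose(volume, basisName)
  out <- lapply(SUBBAND_LABELS, function(lab) {
    f <- intensityFeatures(sb@subbands[[lab]], lesion, nLevels)
    stats::setNames(f, paste0(lab, "_", names(f)))
  })
  unlist(out)
}
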