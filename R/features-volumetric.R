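#' The fixed feature catalog
#'
#' Returns the frozen feature-name catalog per family: 11 shape, 25
#' histogram, 22 GLCM, 16 GLRLM and 14 GLZSM features (88 in total for a
#' volumetric extraction).
#'
#' @return named list of character vectors, one per family.
#' @export
featureCatalog <- function() {
  list(SHAPE = c("SHAPE_volume", "SHAPE_surfaceArea", "SHAPE_surfToVolRatio",
                 "SHAPE_sphericity", "SHAPE_compactness1",
                 "SHAPE_compactness2", "SHAPE_sphericalDisprop",
                 "SHAPE_maxDiameter3D", "SHAPE_majorAxis", "SHAPE_minorAxis",
                 "SHAPE_leastAxis"),
       HIST = c("HIST_mean", "HIST_median", "HIST_min", "HIST_max",
                "HIST_range", "HIST_variance", "HIST_sd", "HIST_skewness",
                "HIST_kurtosis", "HIST_energy", "HIST_rms", "HIST_entropy",
                "HIST_uniformity", "HIST_p5", "HIST_p10", "HIST_p25",
                "HIST_p50", "HIST_p75", "HIST_p90", "HIST_p95", "HIST_iqr",
                "HIST_mad", "HIST_robustMad", "HIST_cov", "HIST_modeBin"),
       GLCM = GLCM_NAMES,
       RL = GLRLM_NAMES,
       GLZSM = GLZSM_NAMES)
}

# The 77 non-shape feature names (histogram + matrix families).
nonShapeFeatureNames <- function() {
  cat <- featureCatalog()
  c(cat$HIST, cat$GLCM, cat$RL, cat$GLZSM)
}

# Histogram + GLCM + GLRLM + GLZSM on one region (77 features).
intensityFeatures <- function(volume, mask, nLevels = 32L) {
  q <- quantizeRegion(volume, mask, nLevels)
  c(histogramFeatures(volume, mask, nLevels),
    glcmFeatures(q), glrlmFeatures(q), glzsmFeatures(q))
}

#' All 88 volumetric features of a lesion
#'
#' Concatenates the shape (11), histogram (25), GLCM (22), GLRLM (16) and
#' GLZSM (14) families computed on the full lesion VOI.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param mask the lesion \linkS4class{RegionMask}.
#' @param nLevels gray levels for quantization (default 32).
#' @return named numeric vector of length 88.
#' @export
volumetricFeatures <- function(volume, mask, nLevels = 32L) {
  checkCompanion(mask, volume)
  c(shapeFeatures(mask), intensityFeatures(volume, mask, nLevels))
}
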