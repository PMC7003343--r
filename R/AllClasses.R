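#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib waveRadiomics, .registration = TRUE
NULL

#' 3D scalar image volume
#'
#' Holds a dense 3D intensity grid (arbitrary MRI units) together with its
#' anisotropic voxel spacing in millimetres. All geometry in the package
#' (band widths, diameters, surface areas) is computed on the voxel grid
#' scaled by this spacing; world coordinates are not used.
#'
#' @slot voxels numeric 3D array of intensities.
#' @slot spacing numeric length-3 vector (dx, dy, dz) in mm, each > 0.
#' @export
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric"))

setValidity("ImageVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("voxels must be a 3D array")
  if (length(object@spacing) != 3L) return("spacing must have length 3")
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    return("spacing must be strictly positive and finite")
  if (any(!is.finite(v))) return("voxel intensities must be finite")
  TRUE
})

#' Binary region mask
#'
#' A binary 3D mask aligned voxel-for-voxel with a companion
#' \linkS4class{ImageVolume}. The \code{regionKind} records whether the mask
#' is a segmented lesion VOI or a peritumoral band.
#'
#' @slot voxels logical 3D array (TRUE = foreground).
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @slot regionKind character, one of \code{"lesion_voi"},
#'   \code{"peripheral_band"}.
#' @export
setClass("RegionMask",
  representation(voxels = "array", spacing = "numeric",
                 regionKind = "character"))

setValidity("RegionMask", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("mask voxels must be a 3D array")
  if (!is.logical(v)) return("mask voxels must be logical")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive numbers")
  if (!object@regionKind %in% c("lesion_voi", "peripheral_band"))
    return("regionKind must be 'lesion_voi' or 'peripheral_band'")
  TRUE
})

#' Gray-level quantized region
#'
#' The result of equal-width min--max discretization of in-mask intensities
#' into \code{nLevels} gray levels; voxels outside the mask carry \code{NA}.
#' All co-occurrence, run-length and zone-size features are computed on this
#' representation, which makes them invariant to intensity shifts.
#'
#' @slot levels integer 3D array with values in 1..nLevels inside the mask,
#'   NA outside.
#' @slot nLevels integer number of gray levels.
#' @slot voxelCount integer number of in-mask voxels.
#' @slot spacing numeric voxel spacing in mm.
#' @export
setClass("QuantizedRegion",
  representation(levels = "array", nLevels = "integer",
                 voxelCount = "integer", spacing = "numeric"))

setValidity("QuantizedRegion", function(object) {
  lv <- object@levels[!is.na(object@levels)]
  if (length(lv) != object@voxelCount)
    return("voxelCount must equal the number of in-mask voxels")
  if (object@voxelCount > 0 &&
      (min(lv) < 1L || max(lv) > object@nLevels))
    return("in-mask levels must lie in [1, nLevels]")
  if (object@nLevels < 1L) return("nLevels must be >= 1")
  TRUE
})

#' Stationary wavelet subband set
#'
#' The eight subbands (LLL ... HHH) of a single-stage undecimated separable
#' 3D wavelet decomposition. Because the transform is stationary, every
#' subband retains the dims and spacing of the input volume, so the original
#' lesion mask applies unchanged to each subband.
#'
#' The label convention is positional: character 1 is the filter applied
#' along X, character 2 along Y, character 3 along Z (L = low-pass,
#' H = high-pass). E.g. LLH is low-pass in X and Y and high-pass in Z.
#'
#' @slot subbands named list of eight 3D arrays.
#' @slot basisName character, wavelet basis (e.g. \code{"haar"}).
#' @slot spacing numeric voxel spacing in mm.
#' @export
setClass("SubbandSet",
  representation(subbands = "list", basisName = "character",
                 spacing = "numeric"))

SUBBAND_LABELS <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

setValidity("SubbandSet", function(object) {
  if (!identical(sort(names(object@subbands)), sort(SUBBAND_LABELS)))
    return("subbands must be named LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH")
  d <- dim(object@subbands[[1L]])
  ok <- vapply(object@subbands, function(a) identical(dim(a), d), logical(1))
  if (!all(ok)) return("all subbands must share the input dims")
  TRUE
})

#' Patients-by-features radiomic table
#'
#' A \linkS4class{SummarizedExperiment} subclass holding the feature matrix
#' (features in rows, patients in columns, assay \code{"features"}), the
#' binary response in \code{colData(x)$response} (levels \code{pCR},
#' \code{nonpCR}) and the feature group (volumetric / peripheral / wavelet)
#' in \code{rowData(x)$featureGroup}.
#'
#' @export
#' @import SummarizedExperiment
setClass("RadiomicFeatureTable", contains = "SummarizedExperiment")

setValidity("RadiomicFeatureTable", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  if (anyDuplicated(rownames(object))) return("feature names must be unique")
  if (anyDuplicated(colnames(object))) return("patient ids must be unique")
  cd <- SummarizedExperiment::colData(object)
  if (!"response" %in% colnames(cd))
    return("colData must contain a 'response' column")
  r <- cd$response
  if (!is.factor(r) || !identical(levels(r), c("nonpCR", "pCR")))
    return("response must be a factor with levels nonpCR, pCR")
  rd <- SummarizedExperiment::rowData(object)
  if (!"featureGroup" %in% colnames(rd))
    return("rowData must contain a 'featureGroup' column")
  if (!all(rd$featureGroup %in% c("volumetric", "peripheral", "wavelet")))
    return("featureGroup must be volumetric, peripheral or wavelet")
  TRUE
})

#' Two-round feature-selection result
#'
#' @slot screened character, features surviving the Boruta-style screen,
#'   ordered by decreasing importance.
#' @slot selected character, final features after iterative AUC culling.
#' @slot importance named numeric importance (mean Z score vs shadows).
#' @slot aucTrace data.frame with columns \code{removed} and \code{auc}; the
#'   first row (removed = NA) is the screened-set AUC, subsequent rows record
#'   each accepted removal. The \code{auc} column is non-decreasing.
#' @export
setClass("SelectionResult",
  representation(screened = "character", selected = "character",
                 importance = "numeric", aucTrace = "data.frame"))

setValidity("SelectionResult", function(object) {
  if (!all(object@selected %in% object@screened))
    return("selected must be a subset of screened")
  if (!all(c("removed", "auc") %in% names(object@aucTrace)))
    return("aucTrace needs 'removed' and 'auc' columns")
  TRUE
})

#' Repeated cross-validation result
#'
#' @slot modelId character model identifier (I--VI or free-form).
#' @slot perRepetition data.frame, one row per repetition with columns
#'   auc, accuracy, sensitivity, specificity.
#' @slot summaries data.frame with mean and sd per metric.
#' @slot rocPoints list of per-repetition pooled ROC coordinate data.frames.
#' @slot features character, the feature set evaluated.
#' @export
setClass("CVResult",
  representation(modelId = "character", perRepetition = "data.frame",
                 summaries = "data.frame", rocPoints = "list",
                 features = "character"))

setValidity("CVResult", function(object) {
  pr <- object@perRepetition
  need <- c("auc", "accuracy", "sensitivity", "specificity")
  if (!all(need %in% names(pr))) return("perRepetition lacks metric columns")
  m <- as.matrix(pr[, need])
  if (nrow(pr) && (min(m) < 0 || max(m) > 1))
    return("metrics must lie in [0, 1]")
  TRUE
})
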