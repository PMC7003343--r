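#' @rdname ImageVolume-class
#' @param x an object.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname ImageVolume-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname RegionMask-class
#' @param x an object.
#' @export
setGeneric("regionKind", function(x) standardGeneric("regionKind"))

#' @rdname RadiomicFeatureTable-class
#' @param x an object.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname RadiomicFeatureTable-class
#' @export
setGeneric("featureGroups", function(x) standardGeneric("featureGroups"))

#' @rdname RadiomicFeatureTable-class
#' @export
setGeneric("responseLabels", function(x) standardGeneric("responseLabels"))

#' @rdname SubbandSet-class
#' @param x an object.
#' @param label subband label, e.g. \code{"HHH"}.
#' @export
setGeneric("subband", function(x, label) standardGeneric("subband"))

#' @rdname SelectionResult-class
#' @param x an object.
#' @export
setGeneric("screenedFeatures", function(x) standardGeneric("screenedFeatures"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname SelectionResult-class
#' @export
setGeneric("featureImportance",
           function(x) standardGeneric("featureImportance"))

#' @rdname SelectionResult-class
#' @export
setGeneric("aucTrace", function(x) standardGeneric("aucTrace"))

#' @rdname CVResult-class
#' @param x an object.
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))

#' @rdname CVResult-class
#' @export
setGeneric("cvSummary", function(x) standardGeneric("cvSummary"))

setMethod("voxels", "ImageVolume", function(x) x@voxels)
setMethod("voxels", "RegionMask", function(x) x@voxels)
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
setMethod("voxelSpacing", "RegionMask", function(x) x@spacing)
setMethod("voxelSpacing", "QuantizedRegion", function(x) x@spacing)
setMethod("voxelSpacing", "SubbandSet", function(x) x@spacing)
setMethod("regionKind", "RegionMask", function(x) x@regionKind)
setMethod("subband", "SubbandSet", function(x, label) {
  if (!label %in% SUBBAND_LABELS) stop("unknown subband label: ", label)
  x@subbands[[label]]
})

setMethod("featureMatrix", "RadiomicFeatureTable", function(x)
  t(SummarizedExperiment::assay(x, "features")))
setMethod("featureGroups", "RadiomicFeatureTable", function(x) {
  g <- SummarizedExperiment::rowData(x)$featureGroup
  names(g) <- rownames(x)
  g
})
setMethod("responseLabels", "RadiomicFeatureTable", function(x) {
  r <- SummarizedExperiment::colData(x)$response
  names(r) <- colnames(x)
  r
})

setMethod("screenedFeatures", "SelectionResult", function(x) x@screened)
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)
setMethod("featureImportance", "SelectionResult", function(x) x@importance)
setMethod("aucTrace", "SelectionResult", function(x) x@aucTrace)

setMethod("cvMetrics", "CVResult", function(x) x@perRepetition)
setMethod("cvSummary", "CVResult", function(x) x@summaries)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "RegionMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("RegionMask (%s) %d x %d x %d, %d foreground voxels\n",
              object@regionKind, d[1], d[2], d[3], sum(object@voxels)))
})

setMethod("show", "SubbandSet", function(object) {
  d <- dim(object@subbands[[1L]])
  cat(sprintf("SubbandSet (%s basis): 8 stationary subbands of %d x %d x %d\n",
              object@basisName, d[1], d[2], d[3]))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d screened -> %d selected\n",
              length(object@screened), length(object@selected)))
  if (length(object@selected))
    cat("  selected:", paste(object@selected, collapse = ", "), "\n")
})

setMethod("show", "CVResult", function(object) {
  s <- object@summaries
  cat(sprintf("CVResult model %s (%d repetitions, %d features)\n",
              object@modelId, nrow(object@perRepetition),
              length(object@features)))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
})
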