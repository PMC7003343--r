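#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file holding a 3D
#'   image with positive voxel spacing.
#' @return an \linkS4class{ImageVolume}; spacing is taken from the header
#'   pixdim, in mm.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D: ", path)
  sp <- RNifti::pixdim(img)[seq_len(3L)]
  if (any(sp <= 0)) stop("non-positive voxel spacing in header: ", path)
  imageVolume(array(as.numeric(img), dim = d), sp)
}

#' Write an ImageVolume to NIfTI-1
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(voxels(volume))
  RNifti::pixdim(img) <- voxelSpacing(volume)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a binary mask aligned with a companion volume
#'
#' Any nonzero voxel in the file becomes foreground (so multi-label
#' segmentations are binarized).
#'
#' @param path NIfTI file path.
#' @param companion the \linkS4class{ImageVolume} the mask belongs to; dims
#'   must match.
#' @param regionKind stored role of the mask.
#' @return a \linkS4class{RegionMask} with the companion's spacing.
#' @export
readMask <- function(path, companion, regionKind = "lesion_voi") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (!identical(d, dim(voxels(companion))))
    stop(sprintf("mask dims (%s) do not match volume dims (%s)",
                 paste(d, collapse = "x"),
                 paste(dim(voxels(companion)), collapse = "x")))
  regionMask(array(as.numeric(img), dim = d),
             spacing = voxelSpacing(companion), regionKind = regionKind)
}

#' Write a RegionMask to NIfTI-1
#' @param mask a \linkS4class{RegionMask}.
#' @param path output path.
#' @export
writeMask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(voxels(mask)),
                               dim = dim(voxels(mask))))
  RNifti::pixdim(img) <- voxelSpacing(mask)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

# Feature group from the naming convention: Bndry_* is peripheral, a
# subband prefix (LLL_ ... HHH_) is wavelet, everything else volumetric.
inferFeatureGroup <- function(featureNames) {
  g <- rep("volumetric", length(featureNames))
  g[startsWith(featureNames, "Bndry_")] <- "peripheral"
  wav <- Reduce(`|`, lapply(paste0(SUBBAND_LABELS, "_"),
                            function(p) startsWith(featureNames, p)))
  g[wav] <- "wavelet"
  g
}

#' Construct a RadiomicFeatureTable
#'
#' @param features numeric matrix, patients in rows (rownames = patient
#'   ids), features in columns (unique colnames).
#' @param labels character or factor of responses (\code{"pCR"} /
#'   \code{"nonpCR"}), one per patient.
#' @param groups optional feature-group vector; by default inferred from the
#'   feature-name prefixes.
#' @return a \linkS4class{RadiomicFeatureTable}.
#' @export
featureTable <- function(features, labels, groups = NULL) {
  features <- as.matrix(features)
  if (nrow(features) == 0L || ncol(features) == 0L)
    stop("feature table must have at least one patient and one feature")
  if (is.null(colnames(features))) stop("features must have column names")
  if (anyDuplicated(colnames(features)))
    stop("duplicate feature names: ",
         paste(unique(colnames(features)[duplicated(colnames(features))]),
               collapse = ", "))
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("P%03d", seq_len(nrow(features)))
  if (is.null(groups)) groups <- inferFeatureGroup(colnames(features))
  resp <- factor(as.character(labels), levels = c("nonpCR", "pCR"))
  if (any(is.na(resp))) stop("labels must be 'pCR' or 'nonpCR'")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(features)),
    rowData = S4Vectors::DataFrame(featureGroup = groups),
    colData = S4Vectors::DataFrame(response = resp,
                                   row.names = rownames(features)))
  new("RadiomicFeatureTable", se)
}

#' Restrict a feature table to feature groups
#' @param x a \linkS4class{RadiomicFeatureTable}.
#' @param groups subset of volumetric / peripheral / wavelet.
#' @export
subsetByGroup <- function(x, groups) {
  keep <- featureGroups(x) %in% groups
  if (!any(keep)) stop("no features in groups: ", paste(groups, collapse = ","))
  x[keep, ]
}

#' Write / read a feature table as CSV
#'
#' One row per patient: \code{patient_id}, \code{response}, then one column
#' per feature. Reading is the exact inverse up to float formatting.
#'
#' @param table a \linkS4class{RadiomicFeatureTable}.
#' @param path CSV path.
#' @export
writeFeatureTable <- function(table, path) {
  m <- featureMatrix(table)
  df <- data.frame(patient_id = rownames(m),
                   response = as.character(responseLabels(table)),
                   m, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  featNames <- setdiff(names(df), c("patient_id", "response"))
  if (anyDuplicated(featNames)) stop("duplicate feature names in ", path)
  m <- as.matrix(df[, featNames, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$patient_id
  featureTable(m, df$response)
}

#' Write / read cohort clinical records as CSV
#'
#' Columns: patient_id, label, age_years, max_diameter_cm, enhancement_type,
#' subtype, regimen.
#'
#' @param records data.frame of cohort records.
#' @param path CSV path.
#' @export
writeCohortRecords <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortRecords
#' @export
readCohortRecords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "label", "age_years", "max_diameter_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort CSV missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$max_diameter_cm <= 0)) stop("max_diameter_cm must be positive")
  df
}
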