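#' Construct an ImageVolume
#'
#' @param voxels numeric 3D array.
#' @param spacing numeric length-3 voxel spacing (dx, dy, dz) in mm.
#' @return an \linkS4class{ImageVolume}.
#' @export
imageVolume <- function(voxels, spacing = c(1, 1, 1)) {
  storage.mode(voxels) <- "double"
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing))
}

#' Construct a RegionMask
#'
#' Any nonzero voxel becomes foreground, so binarization is idempotent.
#'
#' @param voxels 3D array (logical or numeric); nonzero means foreground.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param regionKind \code{"lesion_voi"} or \code{"peripheral_band"}.
#' @return a \linkS4class{RegionMask}.
#' @export
regionMask <- function(voxels, spacing = c(1, 1, 1),
                       regionKind = "lesion_voi") {
  v <- array(as.logical(voxels != 0), dim = dim(voxels))
  new("RegionMask", voxels = v, spacing = as.numeric(spacing),
      regionKind = regionKind)
}

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Derive a child seed from a parent seed and a stage tag; stays below 2^31.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

# AUC of scores for binary labels via the rank (Mann-Whitney) statistic.
# positive = level counted as event (pCR). Ties handled by midranks.
rankAUC <- function(scores, labels, positive = "pCR") {
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# The 13 unique 3D direction offsets at voxel distance 1 (half of the 26
# neighbours; the other half are the negations, covered by symmetrization).
directionOffsets13 <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- offs[, 3] > 0 |
    (offs[, 3] == 0 & offs[, 2] > 0) |
    (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0)
  m <- offs[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

checkCompanion <- function(mask, volume) {
  if (!identical(dim(voxels(mask)), dim(voxels(volume))))
    stop(sprintf("mask dims (%s) do not match volume dims (%s)",
                 paste(dim(voxels(mask)), collapse = "x"),
                 paste(dim(voxels(volume)), collapse = "x")))
  invisible(TRUE)
}
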