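GLCM_NAMES <- c("GLCM_contrast", "GLCM_dissimilar", "GLCM_homo1",
                "GLCM_homo2", "GLCM_energy", "GLCM_entropy",
                "GLCM_correlation", "GLCM_autocorr", "GLCM_clusterShade",
                "GLCM_clusterProm", "GLCM_clusterTend", "GLCM_maxProb",
                "GLCM_sumAvg", "GLCM_sumEntropy", "GLCM_sumVar",
                "GLCM_diffAvg", "GLCM_diffEntro", "GLCM_diffVar",
                "GLCM_infoCorr1", "GLCM_infoCorr2", "GLCM_idmn", "GLCM_idn")

# Haralick-type features of one normalized symmetric co-occurrence matrix.
glcmFeaturesFromP <- function(P) {
  n <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(n) * px); muy <- sum(seq_len(n) * py)
  sx <- sqrt(sum((seq_len(n) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(n) - muy)^2 * py))
  nz <- P > 0
  ent <- -sum(P[nz] * log2(P[nz]))
  # diagonal (difference) and cross-diagonal (sum) distributions
  k_d <- 0:(n - 1)
  p_d <- vapply(k_d, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_s <- 2:(2 * n)
  p_s <- vapply(k_s, function(k) sum(P[(i + j) == k]), numeric(1))
  sumAvg <- sum(k_s * p_s)
  diffAvg <- sum(k_d * p_d)
  nzs <- p_s > 0; nzd <- p_d > 0
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  pxpy <- outer(px, py)
  ok <- nz & pxpy > 0
  hxy1 <- -sum(P[ok] * log2(pxpy[ok]))
  ok2 <- pxpy > 0
  hxy2 <- -sum(pxpy[ok2] * log2(pxpy[ok2]))
  ic1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  ic2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - ent))))
  corr <- if (sx * sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 1
  ij <- i + j - mux - muy
  out <- c(sum((i - j)^2 * P),
           sum(abs(i - j) * P),
           sum(P / (1 + abs(i - j))),
           sum(P / (1 + (i - j)^2)),
           sum(P^2),
           ent,
           corr,
           sum(i * j * P),
           sum(ij^3 * P),
           sum(ij^4 * P),
           sum(ij^2 * P),
           max(P),
           sumAvg,
           -sum(p_s[nzs] * log2(p_s[nzs])),
           sum((k_s - sumAvg)^2 * p_s),
           diffAvg,
           -sum(p_d[nzd] * log2(p_d[nzd])),
           sum((k_d - diffAvg)^2 * p_d),
           ic1,
           ic2,
           sum(P / (1 + ((i - j) / n)^2)),
           sum(P / (1 + abs(i - j) / n)))
  names(out) <- GLCM_NAMES
  out
}

#' Gray-level co-occurrence matrix features
#'
#' Co-occurrence is counted for the 13 unique 3D direction offsets at voxel
#' distance 1, restricted to in-mask voxel pairs, symmetrized and
#' normalized per direction; the 22 Haralick-type features are computed per
#' direction and averaged over the directions that contain at least one
#' pair. A region with no in-mask pair at all (single voxel) returns all
#' zeros with a warning.
#'
#' @param q a \linkS4class{QuantizedRegion}.
#' @return named numeric vector of length 22.
#' @export
glcmFeatures <- function(q) {
  if (q@voxelCount == 0L) stop("empty region")
  offs <- directionOffsets13()
  cnt <- cpp_glcm_counts(q@levels, dim(q@levels), q@nLevels, offs)
  acc <- numeric(length(GLCM_NAMES))
  used <- 0L
  for (d in seq_len(nrow(offs))) {
    Cd <- cnt[, , d]
    tot <- sum(Cd)
    if (tot == 0) next
    acc <- acc + glcmFeaturesFromP(Cd / tot)
    used <- used + 1L
  }
  if (used == 0L) {
    warning("region has no co-occurring voxel pair; GLCM features set to 0")
    return(stats::setNames(numeric(length(GLCM_NAMES)), GLCM_NAMES))
  }
  stats::setNames(acc / used, GLCM_NAMES)
}
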