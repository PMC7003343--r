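GLRLM_NAMES <- c("RL_sre", "RL_lre", "RL_gln", "RL_glnn", "RL_rln",
                 "RL_rlnn", "RL_rp", "RL_glv", "RL_rlv", "RL_re",
                 "RL_lglre", "RL_hglre", "RL_srlgle", "RL_srhgle",
                 "RL_lrlgle", "RL_lrhgle")

# Features of one run-length count matrix (levels x lengths), Np voxels.
glrlmFeaturesFromCounts <- function(C, Np) {
  Nr <- sum(C)
  i <- row(C); j <- col(C)
  p <- C / Nr
  ri <- rowSums(C); rj <- colSums(C)
  mui <- sum(i * p); muj <- sum(j * p)
  nz <- p > 0
  out <- c(sum(p / j^2),
           sum(p * j^2),
           sum(ri^2) / Nr,
           sum(ri^2) / Nr^2,
           sum(rj^2) / Nr,
           sum(rj^2) / Nr^2,
           Nr / Np,
           sum(p * (i - mui)^2),
           sum(p * (j - muj)^2),
           -sum(p[nz] * log2(p[nz])),
           sum(p / i^2),
           sum(p * i^2),
           sum(p / (i^2 * j^2)),
           sum(p * i^2 / j^2),
           sum(p * j^2 / i^2),
           sum(p * i^2 * j^2))
  names(out) <- GLRLM_NAMES
  out
}

#' Gray-level run-length matrix features
#'
#' Runs are maximal colinear same-level in-mask segments along each of the
#' 13 unique 3D directions; the 16 features are computed per direction and
#' averaged. Every nonempty region has at least one run (of length 1) in
#' every direction, so no degenerate case arises.
#'
#' @param q a \linkS4class{QuantizedRegion}.
#' @return named numeric vector of length 16, names prefixed \code{RL_}.
#' @export
glrlmFeatures <- function(q) {
  if (q@voxelCount == 0L) stop("empty region")
  offs <- directionOffsets13()
  maxLen <- max(dim(q@levels))
  cnt <- cpp_rlm_counts(q@levels, dim(q@levels), q@nLevels, offs, maxLen)
  acc <- numeric(length(GLRLM_NAMES))
  for (d in seq_len(nrow(offs)))
    acc <- acc + glrlmFeaturesFromCounts(
      array(cnt[, , d], dim = c(q@nLevels, maxLen)), q@voxelCount)
  stats::setNames(acc / nrow(offs), GLRLM_NAMES)
}
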