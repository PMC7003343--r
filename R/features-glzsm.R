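GLZSM_NAMES <- c("GLZSM_sae", "GLZSM_lae", "GLZSM_gln", "GLZSM_zsn",
                 "GLZSM_zp", "GLZSM_lglze", "GLZSM_hglze", "GLZSM_salgle",
                 "GLZSM_sahgle", "GLZSM_lalgle", "GLZSM_lahgle",
                 "GLZSM_glv", "GLZSM_zsv", "GLZSM_zse")

#' Gray-level zone size matrix features
#'
#' Zones are 26-connected components of equal gray level within the mask.
#' A single zone-size matrix is built (zone counts by level and size) and
#' the 14 features computed on it; zone percentage is the number of zones
#' divided by the number of in-mask voxels, so a constant region of V
#' voxels has GLZSM_zp = 1/V.
#'
#' @param q a \linkS4class{QuantizedRegion}.
#' @return named numeric vector of length 14.
#' @export
glzsmFeatures <- function(q) {
  if (q@voxelCount == 0L) stop("empty region")
  zs <- cpp_zone_sizes(q@levels, dim(q@levels))
  i <- as.numeric(zs[, 1])   # zone gray level
  s <- as.numeric(zs[, 2])   # zone size in voxels
  Nz <- nrow(zs)
  Np <- q@voxelCount
  p <- rep(1 / Nz, Nz)       # each row is one zone
  # aggregated squared marginals need grouping by level / by size
  ri <- tapply(rep(1, Nz), i, sum)
  rs <- tapply(rep(1, Nz), s, sum)
  # cell probabilities for the zone-size entropy
  cell <- table(i, s) / Nz
  cell <- cell[cell > 0]
  mui <- mean(i); mus <- mean(s)
  out <- c(sum(p / s^2),
           sum(p * s^2),
           sum(ri^2) / Nz,
           sum(rs^2) / Nz,
           Nz / Np,
           sum(p / i^2),
           sum(p * i^2),
           sum(p / (i^2 * s^2)),
           sum(p * i^2 / s^2),
           sum(p * s^2 / i^2),
           sum(p * i^2 * s^2),
           sum(p * (i - mui)^2),
           sum(p * (s - mus)^2),
           -sum(cell * log2(cell)))
  stats::setNames(out, GLZSM_NAMES)
}
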