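#' First-order histogram features
#'
#' The 25-feature first-order catalog over raw in-mask intensities. Moments
#' are population moments; skewness and kurtosis (Pearson, not excess) are
#' defined as 0 for a constant region. Entropy, uniformity and the mode bin
#' are computed on the equal-width quantized histogram (\code{nLevels}
#' bins), so entropy is 0 and uniformity 1 iff the region is constant.
#' MAD is the mean absolute deviation from the mean; robust MAD restricts
#' to intensities between the 10th and 90th percentile.
#'
#' @param volume an \linkS4class{ImageVolume} (or 3D array).
#' @param mask a nonempty \linkS4class{RegionMask}.
#' @param nLevels histogram bin count for the entropy-type features.
#' @return named numeric vector of length 25, names prefixed \code{HIST_}.
#' @export
histogramFeatures <- function(volume, mask, nLevels = 32L) {
  v <- if (is(volume, "ImageVolume")) voxels(volume) else volume
  m <- voxels(mask)
  if (!any(m)) stop("empty mask")
  x <- v[m]
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  q <- quantileFeatures <- stats::quantile(x, c(.05, .10, .25, .50, .75, .90, .95),
                                           names = FALSE, type = 7)
  inRobust <- x >= q[2] & x <= q[6]
  xr <- x[inRobust]
  # quantized histogram for entropy / uniformity / mode
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    p <- 1
    modeBin <- 1L
  } else {
    w <- (hi - lo) / nLevels
    lev <- pmin.int(as.integer(floor((x - lo) / w)) + 1L, as.integer(nLevels))
    cnt <- tabulate(lev, nbins = as.integer(nLevels))
    modeBin <- which.max(cnt)
    p <- cnt[cnt > 0] / n
  }
  entropy <- -sum(p * log2(p))
  uniformity <- sum(p^2)
  c(HIST_mean = mu,
    HIST_median = stats::median(x),
    HIST_min = min(x),
    HIST_max = max(x),
    HIST_range = max(x) - min(x),
    HIST_variance = m2,
    HIST_sd = sqrt(m2),
    HIST_skewness = skew,
    HIST_kurtosis = kurt,
    HIST_energy = sum(x^2),
    HIST_rms = sqrt(mean(x^2)),
    HIST_entropy = entropy,
    HIST_uniformity = uniformity,
    HIST_p5 = q[1], HIST_p10 = q[2], HIST_p25 = q[3], HIST_p50 = q[4],
    HIST_p75 = q[5], HIST_p90 = q[6], HIST_p95 = q[7],
    HIST_iqr = q[5] - q[3],
    HIST_mad = mean(abs(x - mu)),
    HIST_robustMad = if (length(xr)) mean(abs(xr - mean(xr))) else 0,
    HIST_cov = if (mu != 0) sqrt(m2) / mu else 0,
    HIST_modeBin = as.numeric(modeBin))
}
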