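# Shared fixtures, all built in code.

# The 4x4x1 four-quadrant toy: quantizes to itself with 4 levels.
toyQuadrant <- function() {
  m <- matrix(c(1, 1, 2, 2,
                1, 1, 2, 2,
                3, 3, 4, 4,
                3, 3, 4, 4), 4, 4, byrow = TRUE)
  generateToyVolume(array(m, c(4, 4, 1)))
}

# Digital ball of the given radius (mm) centred in a cube grid.
digitalBall <- function(radiusMM, spacingMM, marginVox = 4L) {
  nvox <- ceiling(2 * radiusMM / spacingMM) + 2L * marginVox
  co <- (seq_len(nvox) - 0.5) * spacingMM
  ctr <- mean(co)
  ball <- array(FALSE, c(nvox, nvox, nvox))
  for (z in seq_len(nvox))
    ball[, , z] <- outer((co - ctr)^2, (co - ctr)^2, `+`) +
      (co[z] - ctr)^2 <= radiusMM^2
  regionMask(ball, rep(spacingMM, 3))
}

# Random quantized toy array (values are already gray levels).
randomLevelVolume <- function(dims = c(4, 4, 3), nLevels = 4L) {
  generateToyVolume(array(sample.int(nLevels, prod(dims), replace = TRUE),
                          dims))
}

# A tiny cohort configuration for fast pipeline tests.
tinyCohortConfig <- function(nPcr = 4L, nNonPcr = 6L, seed = 1L, ...) {
  syntheticCohortConfig(nPcr = nPcr, nNonPcr = nNonPcr,
                        gridDims = c(24L, 24L, 24L),
                        spacingMM = c(4, 4, 4),
                        diameterMaxCM = 7, seed = seed, ...)
}

# Planted-signal classification toy: one informative feature + noise.
plantedSignalData <- function(n = 200L, nNoise = 20L, seed = 42L) {
  withr::with_seed(seed, {
    y <- factor(rep(c("nonpCR", "pCR"), length.out = n),
                levels = c("nonpCR", "pCR"))
    x <- cbind(signal = as.numeric(y == "pCR") + rnorm(n, sd = 0.3),
               matrix(rnorm(n * nNoise), n,
                      dimnames = list(NULL, paste0("noise", seq_len(nNoise)))))
    list(x = x, y = y)
  })
}
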