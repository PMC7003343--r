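test_that("quantization matches equal-width binning on worked examples", {
  t1 <- generateToyVolume(array(0:31, c(32, 1, 1)))
  expect_identical(quantizeRegion(t1$volume, t1$mask, 32)@levels[, 1, 1], 1:32)
  t2 <- generateToyVolume(array(c(0, 10, 20, 30), c(4, 1, 1)))
  expect_identical(quantizeRegion(t2$volume, t2$mask, 2)@levels[, 1, 1],
                   c(1L, 1L, 2L, 2L))
  t3 <- generateToyVolume(array(7, c(3, 3, 3)))
  expect_true(all(quantizeRegion(t3$volume, t3$mask, 32)@levels == 1L))
  expect_error(quantizeRegion(t3$volume,
                              regionMask(array(FALSE, c(3, 3, 3))), 32),
               "empty")
})

test_that("constant regions give the degenerate closed-form features", {
  cst <- generateToyVolume(array(5, c(5, 5, 5)))
  q <- quantizeRegion(cst$volume, cst$mask, 32)
  g <- glcmFeatures(q)
  expect_equal(g[["GLCM_contrast"]], 0)
  expect_equal(g[["GLCM_dissimilar"]], 0)
  expect_equal(g[["GLCM_homo1"]], 1)
  expect_equal(g[["GLCM_energy"]], 1)
  z <- glzsmFeatures(q)
  expect_equal(z[["GLZSM_zp"]], 1 / 125)  # one zone of 125 voxels
  h <- histogramFeatures(cst$volume, cst$mask)
  expect_equal(unname(h[c("HIST_mean", "HIST_median", "HIST_min",
                          "HIST_max")]), rep(5, 4))
  expect_equal(h[["HIST_variance"]], 0)
  expect_equal(h[["HIST_entropy"]], 0)
  expect_equal(h[["HIST_uniformity"]], 1)
})

test_that("histogram features equal direct formulas on {1,2,3,4}", {
  t4 <- generateToyVolume(array(1:4, c(4, 1, 1)))
  h <- histogramFeatures(t4$volume, t4$mask, nLevels = 4)
  x <- 1:4
  m2 <- mean((x - 2.5)^2)
  expect_equal(h[["HIST_mean"]], 2.5)
  expect_equal(h[["HIST_variance"]], m2)
  expect_equal(h[["HIST_skewness"]], mean((x - 2.5)^3) / m2^1.5)
  expect_equal(h[["HIST_kurtosis"]], mean((x - 2.5)^4) / m2^2)
  expect_equal(h[["HIST_energy"]], sum(x^2))
  expect_equal(h[["HIST_rms"]], sqrt(mean(x^2)))
  expect_equal(h[["HIST_entropy"]], 2)       # 4 equal bins
  expect_equal(h[["HIST_uniformity"]], 0.25)
  expect_equal(h[["HIST_p25"]], unname(quantile(x, 0.25)))
})

test_that("catalog families have the documented sizes and names", {
  cat <- featureCatalog()
  expect_equal(lengths(cat),
               c(SHAPE = 11L, HIST = 25L, GLCM = 22L, RL = 16L, GLZSM = 14L))
  expect_false(anyDuplicated(unlist(cat)) > 0)
  expect_true(all(c("GLCM_homo1", "GLCM_diffEntro", "GLCM_dissimilar",
                    "GLCM_contrast", "GLCM_infoCorr1", "GLCM_correlation",
                    "GLZSM_salgle", "GLZSM_zp", "RL_rln",
                    "SHAPE_surfaceArea") %in% unlist(cat)))
})

test_that("matrix features equal the brute-force oracles on the quadrant toy", {
  toy <- toyQuadrant()
  q <- quantizeRegion(toy$volume, toy$mask, 4)
  expect_equal(q@levels[, , 1], matrix(as.integer(voxels(toy$volume)), 4, 4))
  expect_equal(unname(glcmFeatures(q)), oracleGLCM(q@levels, 4),
               tolerance = 1e-12)
  expect_equal(unname(glrlmFeatures(q)), oracleGLRLM(q@levels, 16),
               tolerance = 1e-12)
  expect_equal(unname(glzsmFeatures(q)), oracleGLZSM(q@levels, 16),
               tolerance = 1e-12)
  # 4 zones of size 4
  expect_equal(glzsmFeatures(q)[["GLZSM_zp"]], 4 / 16)
})

test_that("matrix features equal the oracles on random small arrays", {
  withr::with_seed(7, {
    for (case in 1:12) {
      toy <- randomLevelVolume(c(4, 4, 3), 4)
      q <- quantizeRegion(toy$volume, toy$mask,
                          max(voxels(toy$volume)))
      expect_equal(unname(glcmFeatures(q)), oracleGLCM(q@levels, q@nLevels),
                   tolerance = 1e-10)
      expect_equal(unname(glrlmFeatures(q)),
                   oracleGLRLM(q@levels, q@voxelCount), tolerance = 1e-10)
      expect_equal(unname(glzsmFeatures(q)),
                   oracleGLZSM(q@levels, q@voxelCount), tolerance = 1e-10)
    }
  })
})

test_that("run decomposition is exact on a 1xN constant line", {
  line <- generateToyVolume(array(2, c(1, 1, 5)))
  q <- quantizeRegion(line$volume, line$mask, 2)
  r <- glrlmFeatures(q)
  # 12 directions see 5 runs of length 1 (RP = 1), the z axis one run of 5
  expect_equal(r[["RL_rp"]], (12 * 1 + 1 / 5) / 13)
  expect_equal(unname(r), oracleGLRLM(q@levels, 5), tolerance = 1e-12)
})

test_that("matrix features are invariant to intensity shifts", {
  withr::with_seed(11, {
    toy <- generateToyVolume(array(rnorm(5 * 5 * 4), c(5, 5, 4)))
    shifted <- imageVolume(voxels(toy$volume) + 100, voxelSpacing(toy$volume))
    f1 <- quantizeRegion(toy$volume, toy$mask, 8)
    f2 <- quantizeRegion(shifted, toy$mask, 8)
    expect_identical(f1@levels, f2@levels)
  })
})

test_that("direction-averaged features are invariant to 90-degree rotation", {
  withr::with_seed(13, {
    v <- array(sample.int(4, 4 * 4 * 4, TRUE), c(4, 4, 4))
    a <- generateToyVolume(v)
    b <- generateToyVolume(aperm(v[, 4:1, ], c(2, 1, 3)))  # rotate in XY
    qa <- quantizeRegion(a$volume, a$mask, 4)
    qb <- quantizeRegion(b$volume, b$mask, 4)
    expect_equal(glcmFeatures(qa), glcmFeatures(qb), tolerance = 1e-12)
    expect_equal(glrlmFeatures(qa), glrlmFeatures(qb), tolerance = 1e-12)
    expect_equal(glzsmFeatures(qa), glzsmFeatures(qb), tolerance = 1e-12)
  })
})

test_that("co-occurrence matrices are normalized and non-negative", {
  withr::with_seed(17, {
    toy <- randomLevelVolume(c(4, 4, 3), 4)
    q <- quantizeRegion(toy$volume, toy$mask, 4)
    cnt <- waveRadiomics:::cpp_glcm_counts(
      q@levels, dim(q@levels), q@nLevels,
      waveRadiomics:::directionOffsets13())
    expect_true(all(cnt >= 0))
    for (d in 1:13) {
      Cd <- cnt[, , d]
      if (sum(Cd) > 0) {
        expect_equal(sum(Cd / sum(Cd)), 1)
        expect_equal(Cd, t(Cd))   # symmetrized
      }
    }
  })
})

test_that("a single-voxel region yields flagged all-zero GLCM features", {
  one <- generateToyVolume(array(3, c(1, 1, 1)))
  q <- quantizeRegion(imageVolume(array(c(3), c(1, 1, 1))),
                      one$mask, 2)
  expect_warning(g <- glcmFeatures(q), "no co-occurring")
  expect_true(all(g == 0))
})

test_that("volumetric extraction concatenates all 88 catalog features", {
  withr::with_seed(19, {
    toy <- generateToyVolume(array(rnorm(6 * 6 * 5), c(6, 6, 5)),
                             spacing = c(1, 1, 2))
    f <- volumetricFeatures(toy$volume, toy$mask, nLevels = 8)
    expect_length(f, 88L)
    expect_identical(names(f), unlist(featureCatalog(), use.names = FALSE))
  })
})
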