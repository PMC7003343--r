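test_that("the generator reproduces the configured class design", {
  cfg <- tinyCohortConfig(nPcr = 3L, nNonPcr = 5L, seed = 7L)
  ch <- generateCohort(cfg)
  recs <- cohortRecords(ch)
  expect_length(ch, 8L)
  expect_equal(sum(recs$label == "pCR"), 3L)
  expect_equal(recs$patient_id, sprintf("S%03d", 1:8))
  for (s in ch) {
    expect_s4_class(s$volume, "ImageVolume")
    expect_gt(sum(voxels(s$mask)), 0)
    expect_identical(dim(voxels(s$mask)), dim(voxels(s$volume)))
  }
  expect_true(all(recs$max_diameter_cm > 0.5))
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generateCohort(tinyCohortConfig(seed = 13L))
  b <- generateCohort(tinyCohortConfig(seed = 13L))
  expect_identical(voxels(a[[1]]$volume), voxels(b[[1]]$volume))
  expect_identical(voxels(a[[5]]$mask), voxels(b[[5]]$mask))
  expect_identical(cohortRecords(a), cohortRecords(b))
  c2 <- generateCohort(tinyCohortConfig(seed = 14L))
  expect_false(identical(voxels(a[[1]]$volume), voxels(c2[[1]]$volume)))
})

test_that("sampled diameters track the configured class means", {
  cfg <- tinyCohortConfig(nPcr = 30L, nNonPcr = 30L, seed = 3L)
  recs <- cohortRecords(generateCohort(cfg))
  for (cls in c("pCR", "nonpCR")) {
    d <- recs$max_diameter_cm[recs$label == cls]
    target <- cfg$diameterMeanCM[[cls]]
    se <- cfg$diameterSdCM[[cls]] / sqrt(length(d))
    # allow for the upper truncation shift in addition to 3 SE
    expect_lt(abs(mean(d) - target), 3 * se + 0.35)
  }
})

test_that("an oversized lesion for the grid is an error", {
  cfg <- syntheticCohortConfig(nPcr = 1L, nNonPcr = 1L,
                               gridDims = c(8L, 8L, 8L),
                               spacingMM = c(0.5, 0.5, 0.5))
  expect_error(generateCohort(cfg), "cannot fit")
})

test_that("effectScale zero removes every class difference in the design", {
  cfg <- tinyCohortConfig(effectScale = 0)
  p <- waveRadiomics:::effectivePair(cfg$diameterMeanCM, 0)
  expect_equal(p[["pCR"]], p[["nonpCR"]])
  g <- waveRadiomics:::effectivePair(cfg$textureGrainMM, 0)
  expect_equal(g[["pCR"]], g[["nonpCR"]])
  full <- waveRadiomics:::effectivePair(cfg$diameterMeanCM, 1)
  expect_equal(full, cfg$diameterMeanCM)
})

test_that("toy volumes wrap literal arrays", {
  t1 <- generateToyVolume(array(1:4, c(4, 1, 1)), spacing = c(2, 1, 1))
  expect_equal(c(voxels(t1$volume)), 1:4)
  expect_equal(voxelSpacing(t1$volume), c(2, 1, 1))
  expect_true(all(voxels(t1$mask)))
  t2 <- generateToyVolume(array(9, c(1, 1, 1)))
  expect_identical(dim(voxels(t2$volume)), c(1L, 1L, 1L))
})

test_that("the eligibility filter reproduces the enrollment flow", {
  reg <- syntheticRegistry(83L, c(13L, 2L, 5L, 6L, 2L), seed = 2L)
  res <- applyEligibilityFilter(reg)
  expect_equal(nrow(res$included), 55L)
  expect_equal(unname(res$exclusionCounts), c(13L, 2L, 5L, 6L, 2L))
  # all-false flags: identity
  clean <- reg[rowSums(reg[, waveRadiomics:::ELIGIBILITY_FLAGS]) == 0, ]
  res2 <- applyEligibilityFilter(clean)
  expect_identical(res2$included, clean)
  expect_true(all(res2$exclusionCounts == 0L))
})

test_that("multi-flag records count under the first matching criterion", {
  df <- data.frame(subject_id = c("a", "b"),
                   excl_prior_therapy = c(FALSE, FALSE),
                   excl_mri_nac_interval = c(TRUE, FALSE),
                   excl_artifacts = c(TRUE, FALSE),
                   excl_incomplete_nac = c(FALSE, FALSE),
                   excl_no_surgery = c(TRUE, FALSE))
  res <- applyEligibilityFilter(df)
  expect_equal(nrow(res$included), 1L)
  expect_equal(unname(res$exclusionCounts), c(0L, 1L, 0L, 0L, 0L))
})
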