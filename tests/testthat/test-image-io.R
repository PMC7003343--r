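test_that("volume NIfTI round-trip preserves voxels and spacing", {
  v <- imageVolume(array(rnorm(16 * 16 * 8), c(16, 16, 8)), c(1, 1, 1))
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(v, f)
  v2 <- readVolume(f)
  expect_identical(dim(voxels(v2)), c(16L, 16L, 8L))
  expect_equal(voxelSpacing(v2), c(1, 1, 1))
  expect_identical(c(voxels(v2)), c(voxels(v)))
})

test_that("non-3D NIfTI and missing files are rejected", {
  f <- tempfile(fileext = ".nii.gz")
  img4 <- RNifti::asNifti(array(0, c(4, 4, 4, 2)))
  RNifti::writeNifti(img4, f)
  expect_error(readVolume(f), "3D")
  expect_error(readVolume(tempfile()), "not found")
})

test_that("masks binarize any nonzero label and check dims", {
  vol <- imageVolume(array(0, c(6, 6, 4)))
  lab <- array(0, c(6, 6, 4))
  lab[2:4, 2:4, 2] <- 3        # multi-label foreground
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(lab), f)
  m <- readMask(f, vol)
  expect_identical(sum(voxels(m)), 9L)
  expect_true(is.logical(voxels(m)))
  # binarization idempotent
  expect_identical(voxels(regionMask(voxels(m))), voxels(m))
  small <- imageVolume(array(0, c(5, 5, 4)))
  expect_error(readMask(f, small), "6x6x4")
})

test_that("feature-table CSV round-trip is exact to 1e-12 relative", {
  m <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("P1", "P2"), c("fa", "fb", "fc")))
  ft <- featureTable(m, c("pCR", "nonpCR"))
  f <- tempfile(fileext = ".csv")
  writeFeatureTable(ft, f)
  ft2 <- readFeatureTable(f)
  expect_equal(featureMatrix(ft2), featureMatrix(ft), tolerance = 1e-12)
  expect_identical(as.character(responseLabels(ft2)),
                   as.character(responseLabels(ft)))
  # header: patient_id + response + 3 features
  expect_length(strsplit(readLines(f, n = 1), ",")[[1]], 5L)
})

test_that("feature-table constructor rejects degenerate input", {
  m <- matrix(1:4, 2, 2, dimnames = list(NULL, c("a", "a")))
  expect_error(featureTable(m, c("pCR", "nonpCR")), "duplicate")
  expect_error(featureTable(matrix(numeric(0), 0, 0), character(0)),
               "at least one")
  expect_error(featureTable(matrix(1:2, 2, 1, dimnames = list(NULL, "a")),
                            c("yes", "no")), "labels")
})

test_that("a full 781-feature table writes with the catalog column count", {
  cat <- featureCatalog()
  vol <- unlist(cat)                                       # 88
  per <- paste0("Bndry_", c(cat$HIST, cat$GLCM, cat$RL, cat$GLZSM))  # 77
  wav <- as.vector(vapply(c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH",
                            "HHL", "HHH"),
                          function(s) paste0(s, "_", c(cat$HIST, cat$GLCM,
                                                       cat$RL, cat$GLZSM)),
                          character(77)))                  # 616
  nm <- c(vol, per, wav)
  expect_length(nm, 781L)
  m <- matrix(rnorm(2 * 781), 2, 781, dimnames = list(c("P1", "P2"), nm))
  ft <- featureTable(m, c("pCR", "nonpCR"))
  expect_equal(unname(table(featureGroups(ft))[c("volumetric", "peripheral",
                                                 "wavelet")]),
               c(88L, 77L, 616L), ignore_attr = TRUE)
  f <- tempfile(fileext = ".csv")
  writeFeatureTable(ft, f)
  expect_length(strsplit(readLines(f, n = 1), ",")[[1]], 783L)
})

test_that("cohort record CSV round-trips and validates", {
  rec <- data.frame(patient_id = c("a", "b"), label = c("pCR", "nonpCR"),
                    age_years = c(50, 60), max_diameter_cm = c(2.5, 4.1),
                    enhancement_type = c("mass", "nonmass"),
                    subtype = c("Her2", "TNBC"),
                    regimen = c("EC+Taxol", "Others"))
  f <- tempfile(fileext = ".csv")
  writeCohortRecords(rec, f)
  expect_equal(readCohortRecords(f), rec)
  rec$max_diameter_cm[1] <- -1
  writeCohortRecords(rec, f)
  expect_error(readCohortRecords(f), "positive")
})
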