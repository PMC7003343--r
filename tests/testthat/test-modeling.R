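makeTable <- function(n, p, seed = 1L, labels = NULL) {
  withr::with_seed(seed, {
    if (is.null(labels))
      labels <- rep(c("pCR", "nonpCR"), length.out = n)
    m <- matrix(rnorm(n * p), n,
                dimnames = list(sprintf("P%02d", 1:n),
                                paste0("HIST_f", seq_len(p))))
    featureTable(m, labels)
  })
}

test_that("SMOTE balances a 17/38 cohort to exactly 50 + 50", {
  tab <- makeTable(55, 6, seed = 2,
                   labels = rep(c("pCR", "nonpCR"), c(17, 38)))
  bal <- smoteBalance(tab, 50L, seed = 4L)
  expect_equal(unname(table(responseLabels(bal))), c(50L, 50L),
               ignore_attr = TRUE)
  expect_equal(nrow(featureMatrix(bal)), 100L)
  # originals retained
  expect_true(all(rownames(featureMatrix(tab)) %in%
                    rownames(featureMatrix(bal))))
})

test_that("an already balanced table is returned unchanged", {
  tab <- makeTable(10, 3, seed = 3)
  expect_identical(smoteBalance(tab, 5L), tab)
})

test_that("synthetic samples interpolate within their class envelope", {
  tab <- makeTable(30, 4, seed = 5,
                   labels = rep(c("pCR", "nonpCR"), c(10, 20)))
  bal <- smoteBalance(tab, 25L, seed = 6L)
  m <- featureMatrix(bal)
  y <- responseLabels(bal)
  orig <- featureMatrix(tab)
  oy <- responseLabels(tab)
  for (cls in c("pCR", "nonpCR")) {
    synth <- m[y == cls & startsWith(rownames(m), "syn_"), , drop = FALSE]
    lo <- apply(orig[oy == cls, ], 2, min)
    hi <- apply(orig[oy == cls, ], 2, max)
    expect_true(all(sweep(synth, 2, lo, `>=`)))
    expect_true(all(sweep(synth, 2, hi, `<=`)))
  }
  # determinism
  expect_identical(featureMatrix(smoteBalance(tab, 25L, seed = 6L)), m)
})

test_that("a single-sample class cannot be SMOTEd", {
  tab <- makeTable(5, 3, seed = 7, labels = c("pCR", rep("nonpCR", 4)))
  expect_error(smoteBalance(tab, 10L), "single sample")
})

test_that("the mtry rule rounds the square root up", {
  expect_identical(rfMtry(88), 10L)
  expect_identical(rfMtry(77), 9L)
  expect_identical(rfMtry(616), 25L)
  expect_identical(rfMtry(4), 2L)
})

test_that("a separable toy is perfectly ranked by the forest", {
  withr::with_seed(8, {
    n <- 40
    y <- factor(rep(c("nonpCR", "pCR"), each = n / 2),
                levels = c("nonpCR", "pCR"))
    x <- cbind(f1 = rnorm(n, ifelse(y == "pCR", 5, -5)),
               f2 = rnorm(n))
    fit <- trainRF(x, y, seed = 3L)
    expect_equal(waveRadiomics:::rankAUC(
      waveRadiomics:::rfProb(fit, x), y), 1)
  })
})

test_that("the rank AUC agrees with pROC and is monotone-invariant", {
  skip_if_not_installed("pROC")
  withr::with_seed(10, {
    y <- factor(sample(rep(c("nonpCR", "pCR"), 25)),
                levels = c("nonpCR", "pCR"))
    s <- rnorm(50)
    a1 <- waveRadiomics:::rankAUC(s, y)
    a2 <- as.numeric(pROC::auc(pROC::roc(y, s, levels = c("nonpCR", "pCR"),
                                         direction = "<", quiet = TRUE)))
    expect_equal(a1, a2)
    expect_equal(waveRadiomics:::rankAUC(exp(3 * s), y), a1)
  })
})

test_that("cross-validation is deterministic and metrics stay in range", {
  tab <- makeTable(40, 8, seed = 12)
  a <- crossValidate(tab, "I", nFolds = 5L, nRepetitions = 4L, seed = 9L)
  b <- crossValidate(tab, "I", nFolds = 5L, nRepetitions = 4L, seed = 9L)
  expect_identical(cvMetrics(a), cvMetrics(b))
  m <- as.matrix(cvMetrics(a))
  expect_true(all(m >= 0 & m <= 1))
  s <- cvSummary(a)
  expect_true(all(s$sd >= 0))
  expect_true(all(s$mean >= apply(m, 2, min) & s$mean <= apply(m, 2, max)))
})

test_that("random labels give chance-level cross-validated AUC", {
  # per-dataset null CV AUC is noisy at this n; the expectation over
  # datasets must sit at chance
  aucs <- vapply(1:5, function(k) {
    tab <- makeTable(100, 15, seed = 140 + k,
                     labels = withr::with_seed(150 + k,
                       sample(rep(c("pCR", "nonpCR"), 50))))
    cv <- crossValidate(tab, "I", nFolds = 10L, nRepetitions = 5L,
                        seed = 160 + k)
    cvSummary(cv)$mean[1]
  }, numeric(1))
  expect_gt(mean(aucs), 0.40)
  expect_lt(mean(aucs), 0.60)
})

test_that("model specs map to the six feature-group combinations", {
  expect_equal(modelSpec("I")$groups, "volumetric")
  expect_equal(modelSpec("III")$groups, "wavelet")
  expect_setequal(modelSpec("VI")$groups,
                  c("volumetric", "peripheral", "wavelet"))
  expect_error(modelSpec("VII"), "I..VI")
})

test_that("model comparison matches a closed-form t-test oracle", {
  mk <- function(v) new("CVResult", modelId = "I",
                        perRepetition = data.frame(auc = v, accuracy = v,
                                                   sensitivity = v,
                                                   specificity = v),
                        summaries = data.frame(metric = "auc",
                                               mean = mean(v),
                                               sd = sd(v)),
                        rocPoints = list(), features = "f")
  a <- c(0.8, 0.82, 0.84); b <- c(0.7, 0.72, 0.74)
  p <- compareModels(mk(a), mk(b))
  # Welch t statistic and Student CDF computed directly
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  df <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(p, 2 * pt(-abs(tstat), df))
  expect_equal(compareModels(mk(a), mk(a)), 1)          # identical vectors
  expect_equal(compareModels(mk(rep(0.5, 3)), mk(rep(0.5, 3))), 1)
  big <- compareModels(mk(rnorm(100, 0.9, 0.001)),
                       mk(rnorm(100, 0.5, 0.001)))
  expect_lt(big, 1e-3)
  expect_error(compareModels(mk(a), mk(c(a, 0.7))), "differ")
})

test_that("cohort statistics pick the documented tests", {
  rec1 <- data.frame(label = rep(c("pCR", "nonpCR"), each = 10),
                     age_years = rep(c(40, 50, 60, 70, 55), 4),
                     max_diameter_cm = rep(c(2, 3, 4, 5, 3.5), 4),
                     enhancement_type = rep(c("mass", "nonmass"), 10),
                     subtype = rep(c("LuminalA", "Her2"), 10),
                     regimen = rep(c("EC+Taxol", "Others"), 10))
  st <- cohortStats(rec1)
  expect_true(all(st$p_value == 1))   # identical groups
  # Fisher on a diagonal 2x2 table equals the hypergeometric closed form
  rec2 <- data.frame(label = rep(c("pCR", "nonpCR"), each = 10),
                     enhancement_type = rep(c("mass", "nonmass"), each = 10))
  st2 <- cohortStats(rec2)
  expect_identical(st2$test, "fisher")
  expect_equal(st2$p_value, 2 / choose(20, 10))
  expect_error(cohortStats(data.frame(label = rep("pCR", 4),
                                      age_years = 1:4)), "both classes")
})

test_that("the configured diameter gap is detectable in most cohorts", {
  hits <- vapply(1:10, function(s) {
    recs <- cohortRecords(generateCohort(
      tinyCohortConfig(nPcr = 17L, nNonPcr = 38L, seed = 100L + s)))
    st <- cohortStats(recs)
    st$p_value[st$variable == "max_diameter_cm"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
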