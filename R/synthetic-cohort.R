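#' Configuration for the synthetic lesion cohort
#'
#' Defines the study conditions the generator emulates: 17 pCR / 38 non-pCR
#' subjects; class-dependent maximum lesion diameter (2.9 +/- 1.1 cm pCR vs
#' 4.3 +/- 1.9 cm non-pCR, truncated to [0.5, diameterMaxCM] so lesion and
#' band fit the grid); and a class-dependent intratumoral texture grain (the
#' correlation length of the Gaussian random field inside the lesion), which
#' plants the high-frequency signal that wavelet detail subbands detect.
#'
#' \code{effectScale} interpolates every per-class pair towards its midpoint:
#' 0 makes the classes statistically identical, 1 (default) gives the
#' configured class difference.
#'
#' @param nPcr,nNonPcr class sizes.
#' @param gridDims,spacingMM voxel grid and spacing (mm).
#' @param diameterMeanCM,diameterSdCM per-class (pCR, nonpCR) diameter
#'   normal-distribution parameters in cm.
#' @param diameterMaxCM upper truncation of sampled diameters (cm).
#' @param textureGrainMM per-class correlation length (Gaussian smoothing
#'   sigma, mm) of the intratumoral noise field.
#' @param noiseSd per-class relative amplitude of the intratumoral field.
#' @param effectScale class-separation scale in [0, 1] (and beyond).
#' @param seed integer RNG seed.
#' @return a list of class \code{SyntheticCohortConfig}.
#' @export
syntheticCohortConfig <- function(nPcr = 17L, nNonPcr = 38L,
                                  gridDims = c(48L, 48L, 48L),
                                  spacingMM = c(2, 2, 2),
                                  diameterMeanCM = c(pCR = 2.9, nonpCR = 4.3),
                                  diameterSdCM = c(pCR = 1.1, nonpCR = 1.9),
                                  diameterMaxCM = 7.0,
                                  textureGrainMM = c(pCR = 1.5, nonpCR = 4.0),
                                  noiseSd = c(pCR = 1.0, nonpCR = 1.0),
                                  effectScale = 1.0,
                                  seed = 1L) {
  stopifnot(nPcr >= 1L, nNonPcr >= 1L, all(spacingMM > 0),
            all(diameterMeanCM > 0), effectScale >= 0)
  structure(list(nPcr = as.integer(nPcr), nNonPcr = as.integer(nNonPcr),
                 gridDims = as.integer(gridDims), spacingMM = spacingMM,
                 diameterMeanCM = diameterMeanCM,
                 diameterSdCM = diameterSdCM, diameterMaxCM = diameterMaxCM,
                 textureGrainMM = textureGrainMM, noiseSd = noiseSd,
                 effectScale = effectScale, seed = as.integer(seed),
                 lesionBase = 400, textureAmplitude = 80,
                 backgroundBase = 150, parenchymaSd = 40,
                 parenchymaGrainMM = 8, scannerNoiseSd = 10),
            class = "SyntheticCohortConfig")
}

# per-class pair scaled towards its midpoint by effectScale
effectivePair <- function(pair, effectScale) {
  mid <- mean(pair)
  mid + effectScale * (pair - mid)
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

# Smoothed, variance-normalized Gaussian random field on the grid.
randomField <- function(dims, spacing, grainMM) {
  f <- array(stats::rnorm(prod(dims)), dim = dims)
  if (grainMM > 0) f <- gaussSmooth3D(f, rep(grainMM, 3) / spacing)
  s <- stats::sd(f)
  if (s > 0) f / s else f
}

generateSubject <- function(config, label) {
  cl <- if (label == "pCR") 1L else 2L
  es <- config$effectScale
  dMean <- effectivePair(config$diameterMeanCM, es)[cl]
  dSd <- effectivePair(config$diameterSdCM, es)[cl]
  grain <- effectivePair(config$textureGrainMM, es)[cl]
  amp <- effectivePair(config$noiseSd, es)[cl] * config$textureAmplitude
  dims <- config$gridDims
  sp <- config$spacingMM
  extent <- dims * sp
  feasibleCM <- (min(extent) - 4 * max(sp)) / 10
  if (feasibleCM < 0.5)
    stop("lesion cannot fit in grid: feasible diameter ",
         round(feasibleCM, 2), " cm < 0.5 cm")
  dCM <- rtruncnorm1(dMean, dSd, 0.5, min(config$diameterMaxCM, feasibleCM))
  a <- dCM * 10 / 2                       # max semi-axis, mm
  b <- a * stats::runif(1, 0.70, 0.95)
  c3 <- a * stats::runif(1, 0.70, 0.95)
  semi <- sample(c(a, b, c3))             # random axis assignment
  centre <- extent / 2 + stats::runif(3, -1, 1) * sp
  co <- lapply(1:3, function(k) (seq_len(dims[k]) - 0.5) * sp[k])
  ell <- array(0, dim = dims)
  for (z in seq_len(dims[3])) {
    ell[, , z] <- ((co[[1]] - centre[1]) / semi[1])^2 %o% rep(1, dims[2]) +
      rep(1, dims[1]) %o% ((co[[2]] - centre[2]) / semi[2])^2 +
      ((co[[3]][z] - centre[3]) / semi[3])^2
  }
  m <- ell <= 1
  # a sub-voxel lesion still occupies the voxel containing its centre
  if (!any(m)) m[which.min(ell)] <- TRUE
  parench <- randomField(dims, sp, config$parenchymaGrainMM) *
    config$parenchymaSd
  tex <- randomField(dims, sp, grain) * amp
  vol <- config$backgroundBase + parench
  vol[m] <- config$lesionBase + tex[m]
  vol <- vol + array(stats::rnorm(prod(dims), 0, config$scannerNoiseSd),
                     dim = dims)
  ageMean <- if (label == "pCR") 50.7 else 49.5
  ageSd <- if (label == "pCR") 9.4 else 10.4
  massP <- if (label == "pCR") 11 / 17 else 23 / 38
  subW <- if (label == "pCR") c(5, 2, 5, 5) else c(17, 7, 8, 6)
  regW <- if (label == "pCR") c(4, 7, 2, 4) else c(14, 15, 6, 3)
  rec <- data.frame(
    patient_id = NA_character_, label = label,
    age_years = round(rtruncnorm1(ageMean, ageSd, 18, 90), 1),
    max_diameter_cm = dCM,
    enhancement_type = if (stats::runif(1) < massP) "mass" else "nonmass",
    subtype = sample(c("LuminalA", "LuminalB", "Her2", "TNBC"), 1,
                     prob = subW),
    regimen = sample(c("EC+Taxol", "FEC+Taxol", "AC+Taxol", "Others"), 1,
                     prob = regW),
    stringsAsFactors = FALSE)
  list(volume = imageVolume(vol, sp),
       mask = regionMask(m, sp, "lesion_voi"),
       record = rec)
}

#' Generate a synthetic lesion cohort
#'
#' Draws one subject per configured patient: an axis-aligned ellipsoidal
#' lesion with class-dependent maximum diameter, filled with a
#' class-dependent-grain Gaussian texture field over a smooth
#' parenchyma-like background, plus white scanner noise. Deterministic
#' given \code{config$seed}.
#'
#' @param config a \code{\link{syntheticCohortConfig}}.
#' @return list of subjects, each a list with elements \code{volume},
#'   \code{mask}, \code{record}; pCR subjects first.
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SyntheticCohortConfig"))
  withSeed(config$seed, {
    labels <- c(rep("pCR", config$nPcr), rep("nonpCR", config$nNonPcr))
    subjects <- lapply(labels, function(lb) generateSubject(config, lb))
    for (i in seq_along(subjects))
      subjects[[i]]$record$patient_id <- sprintf("S%03d", i)
    subjects
  })
}

#' Collect the clinical records of a generated cohort
#' @param cohort result of \code{\link{generateCohort}}.
#' @return data.frame of cohort records.
#' @export
cohortRecords <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "record"))
}

#' Wrap a literal array as a toy volume with an all-foreground mask
#'
#' @param values small 3D (or 2D, promoted) numeric array.
#' @param spacing voxel spacing in mm.
#' @return list with elements \code{volume} and \code{mask}.
#' @export
generateToyVolume <- function(values, spacing = c(1, 1, 1)) {
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) stop("values must be a 2D or 3D array")
  list(volume = imageVolume(values, spacing),
       mask = regionMask(array(TRUE, dim(values)), spacing, "lesion_voi"))
}

ELIGIBILITY_FLAGS <- c("excl_prior_therapy", "excl_mri_nac_interval",
                       "excl_artifacts", "excl_incomplete_nac",
                       "excl_no_surgery")

#' Apply the eligibility filter to a subject registry
#'
#' Keeps records with all five exclusion flags FALSE and reports
#' per-criterion exclusion counts. A record with several flags set is
#' counted once, under the first matching criterion in the canonical order
#' (prior therapy; MRI-to-NAC interval; image artifacts; incomplete NAC;
#' no surgical resection), mirroring a sequential eligibility flow.
#'
#' @param registry data.frame with logical columns
#'   \code{excl_prior_therapy}, \code{excl_mri_nac_interval},
#'   \code{excl_artifacts}, \code{excl_incomplete_nac},
#'   \code{excl_no_surgery}.
#' @return list with \code{included} (the eligible subset) and
#'   \code{exclusionCounts} (named integer vector in filter order).
#' @export
applyEligibilityFilter <- function(registry) {
  miss <- setdiff(ELIGIBILITY_FLAGS, names(registry))
  if (length(miss)) stop("registry missing flags: ", paste(miss, collapse = ", "))
  flags <- as.matrix(registry[, ELIGIBILITY_FLAGS])
  first <- apply(flags, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1L] else 0L
  })
  counts <- vapply(seq_along(ELIGIBILITY_FLAGS),
                   function(k) sum(first == k), integer(1))
  names(counts) <- ELIGIBILITY_FLAGS
  list(included = registry[first == 0L, , drop = FALSE],
       exclusionCounts = counts)
}

#' Build a synthetic eligibility registry
#'
#' Constructs a registry of \code{nTotal} records of which
#' \code{sum(exclusionCounts)} carry exclusion flags, attributed per
#' criterion in filter order; a few excluded records additionally carry a
#' later flag, exercising first-match attribution. Row order is shuffled
#' deterministically.
#'
#' @param nTotal registry size (default 83).
#' @param exclusionCounts per-criterion counts in filter order
#'   (default c(13, 2, 5, 6, 2)).
#' @param seed RNG seed.
#' @return data.frame registry.
#' @export
syntheticRegistry <- function(nTotal = 83L,
                              exclusionCounts = c(13L, 2L, 5L, 6L, 2L),
                              seed = 1L) {
  stopifnot(sum(exclusionCounts) <= nTotal)
  withSeed(seed, {
    n <- nTotal
    df <- data.frame(subject_id = sprintf("R%03d", seq_len(n)))
    for (f in ELIGIBILITY_FLAGS) df[[f]] <- FALSE
    at <- 1L
    for (k in seq_along(exclusionCounts)) {
      cnt <- exclusionCounts[k]
      if (cnt > 0L) {
        rows <- at:(at + cnt - 1L)
        df[rows, ELIGIBILITY_FLAGS[k]] <- TRUE
        at <- at + cnt
      }
    }
    # secondary later-criterion flags on some already-excluded records
    excl <- which(rowSums(as.matrix(df[, ELIGIBILITY_FLAGS])) > 0)
    extra <- excl[stats::runif(length(excl)) < 0.2]
    for (r in extra) {
      k <- which(as.logical(df[r, ELIGIBILITY_FLAGS]))[1L]
      if (k < length(ELIGIBILITY_FLAGS))
        df[r, ELIGIBILITY_FLAGS[k + 1L]] <- TRUE
    }
    df[sample(n), , drop = FALSE]
  })
}
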