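#' Extract all three feature groups for one subject
#'
#' Volumetric (88) + peripheral band (77) + wavelet (616) = 781 named
#' features. Group membership is encoded in the names (\code{Bndry_} and
#' subband prefixes) and recovered by \code{\link{featureTable}}.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param mask the lesion \linkS4class{RegionMask}.
#' @param nLevels gray levels for quantization.
#' @param bandInnerMM,bandOuterMM peritumoral band half-widths (mm).
#' @param basisName wavelet basis.
#' @return named numeric vector of length 781.
#' @export
extractSubject <- function(volume, mask, nLevels = 32L, bandInnerMM = 5,
                           bandOuterMM = 5, basisName = "haar") {
  band <- peripheralBandMask(mask, bandInnerMM, bandOuterMM)
  c(volumetricFeatures(volume, mask, nLevels),
    peripheralFeatures(volume, band, nLevels),
    waveletFeatures(volume, mask, nLevels, basisName))
}

#' Pipeline configuration
#'
#' @param cohort a \code{\link{syntheticCohortConfig}}, or a list with
#'   elements \code{volumes} (NIfTI paths), \code{masks} (NIfTI paths) and
#'   \code{records} (cohort data.frame) for an ingested cohort.
#' @param nLevels,bandInnerMM,bandOuterMM,basisName extraction parameters.
#' @param targetPerClass,kNeighbors SMOTE parameters.
#' @param zCutoff,borutaMaxIter,maxScreened,cullReps,cullFolds selection
#'   parameters (\code{cullReps} is the repeated-CV depth inside the
#'   culling loop).
#' @param nTrees,nodeSize random-forest parameters.
#' @param nFolds,nRepetitions evaluation cross-validation parameters.
#' @param models model ids to evaluate (default all six).
#' @param outputDir optional directory for the report bundle.
#' @param seed global seed, fanned out to every stochastic stage.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(cohort = syntheticCohortConfig(),
                           nLevels = 32L, bandInnerMM = 5, bandOuterMM = 5,
                           basisName = "haar", targetPerClass = 50L,
                           kNeighbors = 5L, zCutoff = 0.01,
                           borutaMaxIter = 20L, maxScreened = 30L,
                           cullReps = 5L, cullFolds = 10L,
                           nTrees = 100L, nodeSize = 1L, nFolds = 10L,
                           nRepetitions = 100L,
                           models = c("I", "II", "III", "IV", "V", "VI"),
                           outputDir = NULL, seed = 1L) {
  structure(as.list(environment()), class = "PipelineConfig")
}

loadCohort <- function(cohortSpec, seed) {
  if (inherits(cohortSpec, "SyntheticCohortConfig")) {
    cohortSpec$seed <- deriveSeed(seed, "cohort")
    return(generateCohort(cohortSpec))
  }
  stopifnot(is.list(cohortSpec),
            all(c("volumes", "masks", "records") %in% names(cohortSpec)))
  recs <- cohortSpec$records
  lapply(seq_along(cohortSpec$volumes), function(i) {
    vol <- readVolume(cohortSpec$volumes[[i]])
    list(volume = vol,
         mask = readMask(cohortSpec$masks[[i]], vol),
         record = recs[i, , drop = FALSE])
  })
}

#' Run the full radiomic pipeline
#'
#' Generates (or ingests) the cohort, extracts the 781 features per
#' subject, compares the clinical covariates between classes, balances the
#' classes with SMOTE, runs the two-round feature selection and the
#' repeated cross-validation for every requested model, and assembles the
#' report bundle (per-model summaries, pairwise AUC t-test matrix,
#' selection reports, run manifest). Re-running with an identical config
#' reproduces identical outputs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param verbose print per-stage progress.
#' @return invisibly, a list with elements \code{featureTable},
#'   \code{balancedTable}, \code{records}, \code{cohortStats},
#'   \code{selection}, \code{cv}, \code{summary}, \code{pairwisePValues},
#'   \code{manifest}.
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (verbose) message(...)
  params <- rfParams(config$nTrees, config$nodeSize)

  say("stage: cohort")
  cohort <- loadCohort(config$cohort, config$seed)
  records <- cohortRecords(cohort)

  say("stage: extraction (", length(cohort), " subjects)")
  feats <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    tryCatch(
      extractSubject(s$volume, s$mask, config$nLevels, config$bandInnerMM,
                     config$bandOuterMM, config$basisName),
      error = function(e) stop("extraction failed for subject ",
                               s$record$patient_id, ": ",
                               conditionMessage(e)))
  })
  m <- do.call(rbind, feats)
  rownames(m) <- records$patient_id
  ftab <- featureTable(m, records$label)

  say("stage: cohort statistics")
  cstats <- cohortStats(records)

  say("stage: SMOTE balancing")
  btab <- smoteBalance(ftab, config$targetPerClass, config$kNeighbors,
                       seed = deriveSeed(config$seed, "smote"))

  selection <- list()
  cv <- list()
  for (id in config$models) {
    say("stage: selection, model ", id)
    sel <- selectFeatures(btab, id, params, zCutoff = config$zCutoff,
                          maxIter = config$borutaMaxIter,
                          maxScreened = config$maxScreened,
                          cvReps = config$cullReps,
                          cvFolds = config$cullFolds,
                          seed = deriveSeed(config$seed, paste0("sel", id)))
    selection[[id]] <- sel
    say("stage: cross-validation, model ", id, " (",
        length(selectedFeatures(sel)), " features)")
    cv[[id]] <- crossValidate(btab, id, selectedFeatures(sel), params,
                              config$nFolds, config$nRepetitions,
                              seed = deriveSeed(config$seed,
                                                paste0("cv", id)),
                              keepROC = TRUE)
  }

  summary <- do.call(rbind, lapply(config$models, function(id) {
    s <- cvSummary(cv[[id]])
    data.frame(model = id,
               metric = s$metric, mean = s$mean, sd = s$sd,
               n_features = length(selectedFeatures(selection[[id]])))
  }))
  nm <- length(config$models)
  pmat <- matrix(NA_real_, nm, nm,
                 dimnames = list(config$models, config$models))
  if (nm > 1L)
    for (i in seq_len(nm - 1L))
      for (j in (i + 1L):nm)
        pmat[i, j] <- pmat[j, i] <-
          compareModels(cv[[config$models[i]]], cv[[config$models[j]]])

  manifest <- list(
    package = "waveRadiomics",
    version = as.character(utils::packageVersion("waveRadiomics")),
    r_version = R.version.string,
    seed = config$seed,
    n_subjects = nrow(records),
    n_features = ncol(m),
    models = config$models,
    config = config[setdiff(names(config), "cohort")],
    cohort = if (inherits(config$cohort, "SyntheticCohortConfig"))
      unclass(config$cohort) else "ingested")

  bundle <- list(featureTable = ftab, balancedTable = btab,
                 records = records, cohortStats = cstats,
                 selection = selection, cv = cv, summary = summary,
                 pairwisePValues = pmat, manifest = manifest)
  if (!is.null(config$outputDir)) writeReportBundle(bundle, config$outputDir)
  invisible(bundle)
}

#' Write the pipeline report bundle to disk
#' @param bundle result of \code{\link{runPipeline}}.
#' @param dir output directory (created if missing).
#' @export
writeReportBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeFeatureTable(bundle$featureTable, file.path(dir, "features.csv"))
  writeCohortRecords(bundle$records, file.path(dir, "cohort_records.csv"))
  utils::write.csv(bundle$cohortStats, file.path(dir, "cohort_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$summary, file.path(dir, "model_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$pairwisePValues),
                   file.path(dir, "model_pvalues.csv"))
  for (id in names(bundle$cv))
    utils::write.csv(cvMetrics(bundle$cv[[id]]),
                     file.path(dir, sprintf("metrics_model_%s.csv", id)),
                     row.names = FALSE)
  selJson <- lapply(bundle$selection, function(s)
    list(screened = screenedFeatures(s), selected = selectedFeatures(s),
         auc_trace = aucTrace(s)))
  jsonlite::write_json(selJson, file.path(dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
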