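#' Boruta-style all-relevant feature screening
#'
#' Iteratively augments the table with shadow features (per-feature row
#' permutations), fits a random forest with permutation importance, and
#' compares each real feature's importance Z score against the best shadow.
#' Features beating the best shadow accumulate hits; a binomial test on the
#' hit count accepts (p < alpha, greater) or rejects (p < alpha, less) a
#' feature, and rejected features leave the forest. Features still
#' tentative at \code{maxIter} are kept (conservative). Independently of
#' the binomial decision, any feature whose mean importance Z score falls
#' below \code{zCutoff} is rejected; the default cutoff 0.01 implements the
#' study's literal rejection rule.
#'
#' @param x numeric matrix, samples x features.
#' @param y factor with levels nonpCR, pCR (both present).
#' @param params \code{\link{rfParams}}.
#' @param zCutoff importance Z-score rejection cutoff (default 0.01).
#' @param maxIter screening iterations (default 20).
#' @param alpha binomial decision level (default 0.01).
#' @param maxScreened cap on the screened-set size, keeping the
#'   highest-importance features (default Inf).
#' @param seed RNG seed.
#' @return list with \code{screened} (ordered by decreasing importance)
#'   and \code{importance} (mean Z per input feature).
#' @export
borutaScreen <- function(x, y, params = rfParams(), zCutoff = 0.01,
                         maxIter = 20L, alpha = 0.01, maxScreened = Inf,
                         seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop("need at least one feature")
  if (nlevels(droplevels(y)) < 2L || min(table(y)) < 2L)
    stop("need at least two samples in each class")
  p <- ncol(x)
  status <- rep("tentative", p)
  # zero-variance features carry no importance and cannot enter the forest
  constant <- apply(x, 2L, function(v) max(v) == min(v))
  status[constant] <- "rejected"
  hits <- integer(p)
  iters <- integer(p)
  zsum <- numeric(p)
  if (all(constant)) {
    imp <- stats::setNames(numeric(p), colnames(x))
    return(list(screened = character(0), importance = imp))
  }
  for (it in seq_len(maxIter)) {
    live <- which(status != "rejected")
    if (!length(live)) break
    itSeed <- deriveSeed(seed, paste0("boruta", it))
    z <- withSeed(itSeed, {
      shadows <- apply(x[, live, drop = FALSE], 2L, sample)
      colnames(shadows) <- paste0("shadow_", seq_along(live))
      X <- cbind(x[, live, drop = FALSE], shadows)
      fit <- randomForest::randomForest(
        x = X, y = y, ntree = params$nTrees, nodesize = params$nodeSize,
        mtry = rfMtry(ncol(X)), importance = TRUE)
      zz <- randomForest::importance(fit, type = 1L, scale = TRUE)[, 1L]
      zz[!is.finite(zz)] <- 0
      zz
    })
    nl <- length(live)
    zReal <- z[seq_len(nl)]
    maxShadow <- max(z[-seq_len(nl)])
    hit <- zReal > maxShadow
    hits[live] <- hits[live] + hit
    iters[live] <- iters[live] + 1L
    zsum[live] <- zsum[live] + zReal
    tent <- which(status == "tentative")
    for (f in tent) {
      pg <- stats::pbinom(hits[f] - 1L, iters[f], 0.5, lower.tail = FALSE)
      pl <- stats::pbinom(hits[f], iters[f], 0.5)
      if (pg < alpha) status[f] <- "accepted"
      else if (pl < alpha) status[f] <- "rejected"
    }
  }
  meanZ <- ifelse(iters > 0L, zsum / pmax(iters, 1L), 0)
  names(meanZ) <- colnames(x)
  status[status != "rejected" & meanZ < zCutoff] <- "rejected"
  keep <- which(status != "rejected")
  keep <- keep[order(meanZ[keep], decreasing = TRUE)]
  if (is.finite(maxScreened) && length(keep) > maxScreened)
    keep <- keep[seq_len(maxScreened)]
  list(screened = colnames(x)[keep], importance = meanZ)
}

#' Iterative leave-one-feature-out AUC culling
#'
#' Greedy backward elimination: the cross-validated AUC of the current
#' feature set is compared with that of every one-feature-removed set
#' (same folds for all candidates within an iteration); if the best
#' one-less AUC exceeds the current AUC the feature is dropped and the
#' procedure repeats, otherwise it stops. Ties on the maximum are broken
#' by dropping the feature with the lowest screening importance. The
#' accepted-model AUC trace is strictly increasing by construction and the
#' loop terminates in at most \code{length(screened)} iterations.
#'
#' @param screened character vector of screened feature names.
#' @param x numeric matrix, samples x features (superset of screened).
#' @param y response factor.
#' @param params \code{\link{rfParams}}.
#' @param cvReps,cvFolds repeated-CV settings for the AUC estimate
#'   (default 10 repetitions of 10-fold).
#' @param importance named importance vector for tie-breaking (optional).
#' @param seed RNG seed.
#' @return a \linkS4class{SelectionResult}.
#' @export
iterativeCull <- function(screened, x, y, params = rfParams(),
                          cvReps = 10L, cvFolds = 10L, importance = NULL,
                          seed = 1L) {
  if (!length(screened)) stop("screened set is empty")
  x <- as.matrix(x)[, screened, drop = FALSE]
  if (is.null(importance))
    importance <- stats::setNames(rep(0, length(screened)), screened)
  S <- screened
  currentAUC <- cvMeanAUC(x[, S, drop = FALSE], y, params, cvFolds, cvReps,
                          deriveSeed(seed, "cull0"))
  trace <- data.frame(removed = NA_character_, auc = currentAUC,
                      stringsAsFactors = FALSE)
  iter <- 0L
  while (length(S) > 1L) {
    iter <- iter + 1L
    itSeed <- deriveSeed(seed, paste0("cull", iter))
    cand <- vapply(S, function(f)
      cvMeanAUC(x[, setdiff(S, f), drop = FALSE], y, params, cvFolds,
                cvReps, itSeed), numeric(1))
    best <- max(cand)
    if (best <= currentAUC) break
    ties <- S[cand == best]
    drop <- ties[which.min(importance[ties])]
    S <- setdiff(S, drop)
    currentAUC <- best
    trace <- rbind(trace, data.frame(removed = drop, auc = best,
                                     stringsAsFactors = FALSE))
  }
  new("SelectionResult", screened = screened, selected = S,
      importance = importance[screened], aucTrace = trace)
}

#' Two-round feature selection for one model
#'
#' Round 1: \code{\link{borutaScreen}}; round 2:
#' \code{\link{iterativeCull}} on the screened set. If the screen rejects
#' everything, the top \code{fallbackTop} features by importance are used
#' so the model stays estimable (with a warning).
#'
#' @param table a \linkS4class{RadiomicFeatureTable} (typically balanced).
#' @param model a \code{\link{modelSpec}} or id "I".."VI".
#' @param params \code{\link{rfParams}}.
#' @param zCutoff,maxIter,maxScreened screening controls.
#' @param cvReps,cvFolds culling-CV controls.
#' @param fallbackTop screened-set size when the screen rejects all.
#' @param seed RNG seed.
#' @return a \linkS4class{SelectionResult}.
#' @export
selectFeatures <- function(table, model, params = rfParams(),
                           zCutoff = 0.01, maxIter = 20L, maxScreened = 30L,
                           cvReps = 10L, cvFolds = 10L, fallbackTop = 5L,
                           seed = 1L) {
  if (is.character(model)) model <- modelSpec(model)
  x <- featureMatrix(subsetByGroup(table, model$groups))
  y <- responseLabels(table)
  scr <- borutaScreen(x, y, params, zCutoff = zCutoff, maxIter = maxIter,
                      maxScreened = maxScreened,
                      seed = deriveSeed(seed, "screen"))
  screened <- scr$screened
  if (!length(screened)) {
    warning("screening rejected all features; falling back to top ",
            fallbackTop, " by importance")
    screened <- names(sort(scr$importance, decreasing = TRUE))[
      seq_len(min(fallbackTop, length(scr$importance)))]
  }
  iterativeCull(screened, x, y, params, cvReps = cvReps, cvFolds = cvFolds,
                importance = scr$importance[screened],
                seed = deriveSeed(seed, "cull"))
}
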