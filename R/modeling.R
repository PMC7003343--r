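MODEL_GROUPS <- list(
  I = "volumetric",
  II = c("volumetric", "peripheral"),
  III = "wavelet",
  IV = c("volumetric", "wavelet"),
  V = c("peripheral", "wavelet"),
  VI = c("volumetric", "peripheral", "wavelet"))

#' Feature-group combination of one of the six models
#' @param id one of "I".."VI".
#' @return list with \code{modelId} and \code{groups}.
#' @export
modelSpec <- function(id) {
  id <- as.character(id)
  if (!id %in% names(MODEL_GROUPS)) stop("modelId must be one of I..VI")
  list(modelId = id, groups = MODEL_GROUPS[[id]])
}

#' Random-forest hyperparameters
#'
#' Defaults mirror the study configuration: 100 trees, minimum node size 1
#' and ceil(sqrt(p)) candidate features per split.
#'
#' @param nTrees number of trees.
#' @param nodeSize minimum terminal node size.
#' @return list of class \code{RFParams}.
#' @export
rfParams <- function(nTrees = 100L, nodeSize = 1L) {
  stopifnot(nTrees >= 1L, nodeSize >= 1L)
  structure(list(nTrees = as.integer(nTrees), nodeSize = as.integer(nodeSize)),
            class = "RFParams")
}

#' Per-split candidate feature count
#' @param p number of features in the model.
#' @return ceil(sqrt(p)).
#' @export
rfMtry <- function(p) as.integer(ceiling(sqrt(p)))

#' Train a random-forest classifier
#'
#' Bagged ensemble with the configured tree count, node size and
#' ceil(sqrt(p)) features per split; the class-probability score is the
#' mean tree vote. Deterministic given \code{seed}.
#'
#' @param x numeric matrix, samples x features.
#' @param y factor with levels nonpCR, pCR.
#' @param params an \code{\link{rfParams}} object.
#' @param seed RNG seed.
#' @param importance compute permutation importance.
#' @return a fitted \code{randomForest} object.
#' @export
trainRF <- function(x, y, params = rfParams(), seed = 1L,
                    importance = FALSE) {
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty training table")
  if (nlevels(droplevels(y)) < 2L) stop("need both classes to train")
  withSeed(seed,
    randomForest::randomForest(x = x, y = y, ntree = params$nTrees,
                               nodesize = params$nodeSize,
                               mtry = rfMtry(ncol(x)),
                               importance = importance))
}

rfProb <- function(fit, x) {
  stats::predict(fit, newdata = x, type = "prob")[, "pCR"]
}

#' SMOTE class balancing
#'
#' Each class is independently oversampled to exactly
#' \code{targetPerClass} rows by interpolating uniformly on segments
#' between a random original sample and one of its \code{kNeighbors}
#' nearest same-class neighbours (Euclidean in feature space). Original
#' rows are retained; with both classes already at the target the table is
#' returned unchanged. Deterministic given \code{seed}.
#'
#' @param table a \linkS4class{RadiomicFeatureTable}.
#' @param targetPerClass target size per class (default 50, giving the
#'   100-sample balanced design for a 17/38 cohort).
#' @param kNeighbors neighbour pool size (default 5).
#' @param seed RNG seed.
#' @return a balanced \linkS4class{RadiomicFeatureTable}.
#' @export
smoteBalance <- function(table, targetPerClass = 50L, kNeighbors = 5L,
                         seed = 1L) {
  m <- featureMatrix(table)
  y <- responseLabels(table)
  if (all(table(y) == targetPerClass)) return(table)
  withSeed(seed, {
    pieces <- list()
    labs <- list()
    for (cls in levels(y)) {
      X <- m[y == cls, , drop = FALSE]
      n0 <- nrow(X)
      if (n0 > targetPerClass)
        stop("class ", cls, " has ", n0,
             " samples, above the target; only oversampling is supported")
      if (n0 < 2L && n0 < targetPerClass)
        stop("class ", cls, " has a single sample; SMOTE needs a neighbour")
      need <- targetPerClass - n0
      synth <- NULL
      if (need > 0L) {
        k <- min(kNeighbors, n0 - 1L)
        D <- as.matrix(stats::dist(X))
        diag(D) <- Inf
        nn <- apply(D, 1L, function(r) order(r)[seq_len(k)])
        nn <- matrix(nn, nrow = k)
        synth <- matrix(0, need, ncol(X),
                        dimnames = list(NULL, colnames(X)))
        donors <- sample.int(n0, need, replace = TRUE)
        for (s in seq_len(need)) {
          dnr <- donors[s]
          nb <- nn[sample.int(k, 1L), dnr]
          g <- stats::runif(1)
          synth[s, ] <- X[dnr, ] + g * (X[nb, ] - X[dnr, ])
        }
        rownames(synth) <- sprintf("syn_%s_%02d", cls, seq_len(need))
      }
      pieces[[cls]] <- rbind(X, synth)
      labs[[cls]] <- rep(cls, targetPerClass)
    }
    out <- do.call(rbind, pieces)
    featureTable(out, unlist(labs),
                 groups = as.character(featureGroups(table)))
  })
}

# Stratified fold assignment; every fold gets both classes where possible.
stratifiedFolds <- function(y, nFolds, seed) {
  withSeed(seed, {
    fold <- integer(length(y))
    for (cls in levels(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    fold
  })
}

cvOneRepetition <- function(x, y, nFolds, params, seed, roc = FALSE) {
  for (attempt in 1:20) {
    fold <- stratifiedFolds(y, nFolds, seed + attempt - 1L)
    tab <- table(fold, y)
    if (all(tab > 0) || nlevels(y) < 2L) break
    if (attempt == 20L) stop("could not stratify folds with both classes")
  }
  prob <- numeric(length(y))
  for (f in seq_len(nFolds)) {
    tr <- fold != f
    fit <- trainRF(x[tr, , drop = FALSE], y[tr], params,
                   seed = seed + 1000L * f)
    prob[!tr] <- rfProb(fit, x[!tr, , drop = FALSE])
  }
  pred <- factor(ifelse(prob >= 0.5, "pCR", "nonpCR"),
                 levels = c("nonpCR", "pCR"))
  pos <- y == "pCR"
  res <- list(auc = rankAUC(prob, y),
              accuracy = mean(pred == y),
              sensitivity = mean(pred[pos] == "pCR"),
              specificity = mean(pred[!pos] == "nonpCR"))
  if (roc) {
    th <- sort(unique(c(-Inf, prob, Inf)), decreasing = TRUE)
    res$roc <- data.frame(
      fpr = vapply(th, function(t) mean(prob[!pos] >= t), numeric(1)),
      tpr = vapply(th, function(t) mean(prob[pos] >= t), numeric(1)))
  }
  res
}

#' Repeated stratified k-fold cross-validation of one model
#'
#' Per repetition: a stratified fold split, out-of-fold class
#' probabilities pooled over the folds, and one AUC / accuracy /
#' sensitivity / specificity (binary decisions at probability 0.5).
#' Summaries are mean and SD over repetitions.
#'
#' @param table a \linkS4class{RadiomicFeatureTable} (typically
#'   SMOTE-balanced).
#' @param model a \code{\link{modelSpec}} or a model id "I".."VI".
#' @param selected optional character vector restricting to the selected
#'   features; NULL uses all features of the model's groups.
#' @param params \code{\link{rfParams}}.
#' @param nFolds folds per repetition (default 10).
#' @param nRepetitions repetitions (default 100).
#' @param seed RNG seed.
#' @param keepROC store pooled ROC points per repetition.
#' @return a \linkS4class{CVResult}.
#' @export
crossValidate <- function(table, model, selected = NULL,
                          params = rfParams(), nFolds = 10L,
                          nRepetitions = 100L, seed = 1L, keepROC = FALSE) {
  if (is.character(model)) model <- modelSpec(model)
  x <- featureMatrix(subsetByGroup(table, model$groups))
  if (!is.null(selected)) {
    miss <- setdiff(selected, colnames(x))
    if (length(miss)) stop("selected features not in table: ",
                           paste(miss, collapse = ", "))
    x <- x[, selected, drop = FALSE]
  }
  y <- responseLabels(table)
  if (length(y) < nFolds) stop("need at least nFolds samples")
  reps <- lapply(seq_len(nRepetitions), function(r)
    cvOneRepetition(x, y, nFolds, params,
                    deriveSeed(seed, paste0("rep", r)), roc = keepROC))
  pr <- data.frame(auc = vapply(reps, `[[`, numeric(1), "auc"),
                   accuracy = vapply(reps, `[[`, numeric(1), "accuracy"),
                   sensitivity = vapply(reps, `[[`, numeric(1), "sensitivity"),
                   specificity = vapply(reps, `[[`, numeric(1), "specificity"))
  summ <- data.frame(metric = names(pr),
                     mean = vapply(pr, mean, numeric(1)),
                     sd = vapply(pr, stats::sd, numeric(1)),
                     row.names = NULL)
  new("CVResult", modelId = model$modelId, perRepetition = pr,
      summaries = summ,
      rocPoints = if (keepROC) lapply(reps, `[[`, "roc") else list(),
      features = colnames(x))
}

# Light-weight repeated-CV mean AUC used inside the culling loop.
cvMeanAUC <- function(x, y, params, nFolds, nReps, seed) {
  mean(vapply(seq_len(nReps), function(r)
    cvOneRepetition(x, y, nFolds, params,
                    deriveSeed(seed, paste0("rep", r)))$auc, numeric(1)))
}

#' Compare two models' repetition-level AUCs
#'
#' Two-sample t-test (unpaired by default) on the per-repetition AUC
#' vectors; identical constant vectors give p = 1 by convention.
#'
#' @param a,b \linkS4class{CVResult} objects with equal repetition counts.
#' @param paired paired t-test instead of unpaired.
#' @return two-sided p-value.
#' @export
compareModels <- function(a, b, paired = FALSE) {
  va <- cvMetrics(a)$auc
  vb <- cvMetrics(b)$auc
  if (length(va) != length(vb)) stop("repetition counts differ")
  if (stats::sd(va) == 0 && stats::sd(vb) == 0)
    return(if (isTRUE(all.equal(mean(va), mean(vb)))) 1 else 0)
  stats::t.test(va, vb, paired = paired)$p.value
}
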