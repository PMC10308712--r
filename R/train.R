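#' Training configuration
#'
#' Mini-batch Adam with validation-based early stopping.  Defaults follow
#' the published selection: learning rate 0.0003, batch size 30, margin
#' 2.0 (inside `weights`).  The stopping rule (patience 20 on validation
#' total loss, cap 300 epochs) is the package's own choice.
#'
#' @param learningRate Adam step size (> 0).
#' @param batchSize mini-batch size (>= 2 so contrastive pairs exist).
#' @param maxEpochs epoch cap.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed for initialization-independent shuffling.
#' @param weights a [lossWeights()].
#' @param threshold score threshold for the predicted class (default 0.5
#'   on the short-class probability).
#' @param select which parameters [trainOneRound()] returns: `"best"`
#'   (the best-validation-loss checkpoint, the default used for
#'   classification) or `"final"` (the last epoch — the optimization
#'   endpoint, appropriate when studying the constraint terms, whose
#'   late convergence a validation-selected checkpoint does not show).
#' @return a `trainConfig` list.
#' @export
trainConfig <- function(learningRate = 3e-4, batchSize = 30L,
                        maxEpochs = 300L, patience = 20L, seed = 1L,
                        weights = lossWeights(), threshold = 0.5,
                        select = c("best", "final")) {
  select <- match.arg(select)
  assertThat(learningRate > 0, "learningRate must be > 0")
  assertThat(batchSize >= 2, "batchSize must be >= 2")
  stopifnot(inherits(weights, "lossWeights"))
  cfg <- list(
    learningRate = learningRate, batchSize = as.integer(batchSize),
    maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
    seed = as.integer(seed), weights = weights, threshold = threshold,
    select = select
  )
  class(cfg) <- "trainConfig"
  cfg
}

cohortInputs <- function(cohort) {
  lapply(modalities(cohort), function(om) unname(values(om)))
}

sliceInputs <- function(xs, idx) {
  lapply(xs, function(m) m[idx, , drop = FALSE])
}

## batches of indices; a trailing singleton is folded into the previous
## batch so every batch can form contrastive pairs
makeBatches <- function(idx, batchSize) {
  n <- length(idx)
  starts <- seq(1L, n, by = batchSize)
  batches <- lapply(starts, function(s) idx[s:min(s + batchSize - 1L, n)])
  nb <- length(batches)
  if (nb > 1L && length(batches[[nb]]) < 2L) {
    batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
    batches[[nb]] <- NULL
  }
  batches
}

#' Train a model on one train/validation split
#'
#' Mini-batch gradient descent (Adam) on the weighted total loss, with the
#' per-epoch validation total loss deciding early stopping and model
#' selection: the parameters achieving the best validation loss are
#' returned.  Fully deterministic given `config$seed` (seeded shuffling;
#' initialization is seeded in [buildModel()]).  Non-finite training loss
#' aborts with an error.
#'
#' @param cohort a [MultiOmicsCohort-class].
#' @param trainIdx,valIdx disjoint integer sample indices.
#' @param model an `ssnModel` (freshly built or warm).
#' @param config a [trainConfig()].
#' @return list with `model` (best-validation parameters), `log`
#'   (data.frame: epoch, lCE, lDiff, lDiss, lCon, total, valTotal),
#'   `bestEpoch`, `bestVal`.
#' @export
trainOneRound <- function(cohort, trainIdx, valIdx, model, config) {
  assertThat(
    !length(intersect(trainIdx, valIdx)),
    "train and validation indices must be disjoint"
  )
  xs <- cohortInputs(cohort)
  labels <- cohortLabels(cohort)
  trainWorker(
    model, xs, labels, trainIdx, valIdx, config
  )
}

trainWorker <- function(model, xs, labels, trainIdx, valIdx, config) {
  weights <- config$weights
  xsVal <- sliceInputs(xs, valIdx)
  yVal <- labels[valIdx]
  ## private parameter copy; the optimizer updates its leaves in place
  model$params <- duplicateTree(model$params)
  leaves <- collectLeafRefs(model$params)
  mState <- lapply(leaves, function(x) x * 0)
  vState <- lapply(leaves, function(x) x * 0)
  stepT <- 0L
  bestVal <- Inf
  bestVec <- flattenNumericLeaves(model$params)
  bestEpoch <- 0L
  sinceBest <- 0L
  logRows <- vector("list", config$maxEpochs)
  withSeed(config$seed, {
    for (epoch in seq_len(config$maxEpochs)) {
      order <- sample(trainIdx)
      batches <- makeBatches(order, config$batchSize)
      comp <- c(lCE = 0, lDiff = 0, lDiss = 0, lCon = 0, total = 0)
      for (b in batches) {
        res <- modelLoss(model, sliceInputs(xs, b), labels[b], weights,
          grad = TRUE
        )
        rep <- res$report
        if (!all(is.finite(c(rep$total, rep$lCE, rep$lDiff, rep$lDiss, rep$lCon)))) {
          stop(
            "training diverged at epoch ", epoch,
            ": non-finite loss", call. = FALSE
          )
        }
        comp <- comp + c(rep$lCE, rep$lDiff, rep$lDiss, rep$lCon, rep$total)
        gl <- collectGradLeaves(model$params, res$grads)
        stepT <- stepT + 1L
        for (i in seq_along(leaves)) {
          adamUpdateInplace(
            leaves[[i]], gl[[i]], mState[[i]], vState[[i]],
            stepT, config$learningRate, 0.9, 0.999, 1e-8
          )
        }
      }
      comp <- comp / length(batches)
      valRep <- modelLoss(model, xsVal, yVal, weights, grad = FALSE)$report
      logRows[[epoch]] <- data.frame(
        epoch = epoch, lCE = comp[["lCE"]], lDiff = comp[["lDiff"]],
        lDiss = comp[["lDiss"]], lCon = comp[["lCon"]],
        total = comp[["total"]], valTotal = valRep$total
      )
      if (valRep$total < bestVal - 1e-12) {
        bestVal <- valRep$total
        bestVec <- flattenNumericLeaves(model$params)
        bestEpoch <- epoch
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config$patience) break
      }
    }
  })
  ## return the selected parameters (fresh, un-aliased tree)
  if (is.null(config$select) || config$select == "best") {
    model$params <- fillNumericLeaves(duplicateTree(model$params), bestVec)
  } else {
    model$params <- duplicateTree(model$params)
  }
  list(
    model = model,
    log = do.call(rbind, logRows[!vapply(logRows, is.null, TRUE)]),
    bestEpoch = bestEpoch, bestVal = bestVal
  )
}

#' Score samples with a trained model
#'
#' @param model a trained `ssnModel`.
#' @param cohort a [MultiOmicsCohort-class].
#' @param idx optional sample indices (default all).
#' @return numeric vector of short-class probabilities.
#' @export
predictRisk <- function(model, cohort, idx = NULL) {
  xs <- cohortInputs(cohort)
  if (!is.null(idx)) xs <- sliceInputs(xs, idx)
  forwardModel(model, xs)$scoreShort
}

defaultMappingSpec <- function(cohort, mapping = NULL) {
  if (!is.null(mapping)) {
    return(mapping)
  }
  mappingSpec(vapply(modalities(cohort), function(m) ncol(values(m)), 0L))
}

#' Run the stratified ten-fold protocol
#'
#' Trains a freshly initialized model per round (seeded `config$seed + r`),
#' scores that round's test samples, and aggregates per-sample scores by
#' averaging over the rounds in which the sample was tested (exactly two
#' under the cyclic rotation).  No test sample influences training or
#' model selection — early stopping uses the validation subset only.
#'
#' @param cohort a [MultiOmicsCohort-class].
#' @param plan a [FoldPlan-class] built from the cohort's labels.
#' @param config a [trainConfig()].
#' @param net a [netConfig()].
#' @param mapping optional [mappingSpec()] (default derived from the
#'   cohort's dimensions).
#' @param tieSharedWeights passed to [buildModel()].
#' @return a `CVResult` list: `roundScores` (N x rounds matrix, NA where
#'   not tested), `aggregatedScore`, `labels`, `perRound` (metrics per
#'   round), `report` (aggregate [EvalReport][classificationMetrics]),
#'   `auc`, `config`.
#' @export
runCrossValidation <- function(cohort, plan, config = trainConfig(),
                               net = netConfig(), mapping = NULL,
                               tieSharedWeights = FALSE) {
  mapping <- defaultMappingSpec(cohort, mapping)
  xs <- cohortInputs(cohort)
  labels <- cohortLabels(cohort)
  n <- nSamples(cohort)
  nRounds <- plan@nFolds
  roundScores <- matrix(NA_real_, n, nRounds)
  perRound <- vector("list", nRounds)
  for (r in seq_len(nRounds)) {
    rd <- foldRound(plan, r)
    model <- buildModel(mapping, net,
      seed = config$seed + r,
      tieSharedWeights = tieSharedWeights
    )
    cfg <- config
    cfg$seed <- config$seed + r
    fit <- trainWorker(model, xs, labels, rd$train, rd$validation, cfg)
    sc <- forwardModel(
      fit$model,
      sliceInputs(xs, rd$test)
    )$scoreShort
    roundScores[rd$test, r] <- sc
    yPred <- ifelse(sc >= config$threshold, 0L, 1L)
    counts <- confusionCounts(labels[rd$test], yPred)
    perRound[[r]] <- c(
      classificationMetrics(counts),
      list(counts = counts, bestEpoch = fit$bestEpoch)
    )
  }
  tested <- rowSums(!is.na(roundScores)) > 0
  aggregatedScore <- rowMeans(roundScores, na.rm = TRUE)
  yPred <- ifelse(aggregatedScore >= config$threshold, 0L, 1L)
  counts <- confusionCounts(labels[tested], yPred[tested])
  report <- classificationMetrics(counts)
  roc <- rocAuc(labels[tested], aggregatedScore[tested])
  out <- list(
    roundScores = roundScores, aggregatedScore = aggregatedScore,
    labels = labels, perRound = perRound, counts = counts,
    report = report, roc = roc$roc, auc = roc$auc, config = config
  )
  class(out) <- "CVResult"
  out
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf(
    "CVResult: %d rounds, aggregate Acc %.3f, Recall %.3f, Pre %.3f, AUC %.3f\n",
    ncol(x$roundScores), x$report$acc, x$report$recall,
    x$report$precision, x$auc
  ))
  invisible(x)
}

#' Compare layer-by-layer constraints against the last-layer-only ablation
#'
#' Runs [runCrossValidation()] twice with identical seeds and folds: once
#' with the distance/orthogonality penalties on every branch layer (the
#' full method) and once imposing constraints only on the last layer
#' (ICLL), then reports per-metric deltas (full minus ICLL).
#'
#' @inheritParams runCrossValidation
#' @return list with `full`, `icll` (both `CVResult`) and `delta`
#'   (named numeric: acc, recall, precision, auc).
#' @export
runAblationICLL <- function(cohort, plan, config = trainConfig(),
                            net = netConfig(), mapping = NULL) {
  cfgFull <- config
  cfgFull$weights$constraintLayers <- NULL
  cfgIcll <- config
  cfgIcll$weights$constraintLayers <- "last"
  full <- runCrossValidation(cohort, plan, cfgFull, net, mapping)
  icll <- runCrossValidation(cohort, plan, cfgIcll, net, mapping)
  delta <- c(
    acc = full$report$acc - icll$report$acc,
    recall = full$report$recall - icll$report$recall,
    precision = full$report$precision - icll$report$precision,
    auc = full$auc - icll$auc
  )
  list(full = full, icll = icll, delta = delta)
}

#' Write a per-epoch training log as CSV
#'
#' @param log the `log` data.frame from [trainOneRound()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrainingLog <- function(log, path) {
  write.table(log, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
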