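smallTrainSetup <- function(n = 50, seed = 21, ...) {
  gen <- tinyCohort(
    n = n, dims = c(20, 10, 15), seed = seed,
    sharedEffect = 1.2, specificEffects = c(0, 0, 0), ...
  )
  list(
    cohort = gen$cohort,
    map = mappingSpec(c(20, 10, 15)),
    net = tinyNet()
  )
}

test_that("batching keeps every batch large enough for pairs", {
  makeBatches <- ssfuse:::makeBatches
  # a trailing singleton is folded into the previous batch
  b <- makeBatches(1:7, 3)
  expect_length(b, 2L)
  expect_identical(b[[2]], c(4L, 5L, 6L, 7L))
  expect_identical(makeBatches(1:6, 3), list(1:3, 4:6))
  expect_identical(sort(unlist(makeBatches(sample(1:31), 10))), 1:31)
  expect_true(all(lengths(makeBatches(1:31, 10)) >= 2))
})

test_that("training is deterministic and selects the best-validation epoch", {
  s <- smallTrainSetup()
  cfg <- trainConfig(
    learningRate = 1e-3, batchSize = 10, maxEpochs = 8,
    patience = 8, seed = 3
  )
  m <- buildModel(s$map, s$net, seed = 3)
  f1 <- trainOneRound(s$cohort, 1:40, 41:50, m, cfg)
  f2 <- trainOneRound(s$cohort, 1:40, 41:50, m, cfg)
  expect_identical(f1$bestVal, f2$bestVal)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$log, f2$log)
  # the reported best epoch attains the minimum logged validation loss
  expect_equal(f1$bestVal, min(f1$log$valTotal))
  expect_equal(f1$bestEpoch, which.min(f1$log$valTotal))
  # the caller's model is untouched by in-place optimizer updates
  expect_identical(m$params, buildModel(s$map, s$net, seed = 3)$params)
  expect_error(trainOneRound(s$cohort, 1:40, 40:50, m, cfg), "disjoint")
})

test_that("with auxiliary weights zero, training reduces to cross-entropy", {
  s <- smallTrainSetup()
  cfg <- trainConfig(
    learningRate = 1e-3, batchSize = 10, maxEpochs = 5, patience = 5,
    seed = 2, weights = lossWeights(wDiff = 0, wDiss = 0, wCon = 0)
  )
  fit <- trainOneRound(
    s$cohort, 1:40, 41:50,
    buildModel(s$map, s$net, seed = 2), cfg
  )
  expect_equal(fit$log$total, fit$log$lCE)
})

test_that("training separates a noiseless linearly separable cohort", {
  gen <- tinyCohort(
    n = 60, dims = c(20, 10, 15), seed = 5,
    sharedEffect = 1.5, specificEffects = c(0, 0, 0), noiseSd = 0
  )
  cfg <- trainConfig(
    learningRate = 1e-3, batchSize = 15, maxEpochs = 120,
    patience = 120, seed = 7
  )
  fit <- trainOneRound(
    gen$cohort, 1:48, 49:60,
    buildModel(mappingSpec(c(20, 10, 15)), tinyNet(), seed = 7), cfg
  )
  sc <- predictRisk(fit$model, gen$cohort, 1:48)
  trainAcc <- mean(ifelse(sc >= 0.5, 0L, 1L) == cohortLabels(gen$cohort)[1:48])
  expect_gte(trainAcc, 0.98)
  # oracle: the planted latents themselves are separable by a logistic fit
  Z <- gen$truth$zShared
  y <- cohortLabels(gen$cohort)
  orc <- suppressWarnings(glm(y ~ Z, binomial))
  expect_gte(mean((fitted(orc) > 0.5) == y), 0.98)
})

test_that("a single-class batch only contributes same-class pairs, no error", {
  gen <- tinyCohort(n = 30, dims = c(20, 10, 15), seed = 9)
  y <- cohortLabels(gen$cohort)
  oneClass <- which(y == 0)[1:10]
  xs <- lapply(modalities(gen$cohort), function(o) unname(values(o)))
  model <- buildModel(mappingSpec(c(20, 10, 15)), tinyNet(), seed = 1)
  res <- modelLoss(
    model, lapply(xs, function(m) m[oneClass, ]), y[oneClass],
    lossWeights(), grad = TRUE
  )
  expect_true(is.finite(res$report$lCon))
  expect_gte(res$report$lCon, 0)
})

test_that("cross-validation scores every sample in exactly two rounds", {
  s <- smallTrainSetup(n = 60, seed = 33)
  plan <- makeFoldPlan(cohortLabels(s$cohort), seed = 2)
  cfg <- trainConfig(
    learningRate = 1e-3, batchSize = 15, maxEpochs = 3,
    patience = 3, seed = 11
  )
  cv <- runCrossValidation(s$cohort, plan, cfg, s$net, s$map)
  testedPerSample <- rowSums(!is.na(cv$roundScores))
  expect_true(all(testedPerSample == 2L))
  expect_equal(
    cv$aggregatedScore,
    rowMeans(cv$roundScores, na.rm = TRUE)
  )
  # identical seeds and fold plan reproduce the CVResult bit for bit
  cv2 <- runCrossValidation(s$cohort, plan, cfg, s$net, s$map)
  expect_identical(cv$roundScores, cv2$roundScores)
  expect_identical(cv$report, cv2$report)
})

test_that("test samples never influence training or model selection", {
  # sentinel: corrupt the features of round-1 test samples; the model
  # trained in round 1 must come out identical
  s <- smallTrainSetup(n = 60, seed = 41)
  plan <- makeFoldPlan(cohortLabels(s$cohort), seed = 8)
  rd <- foldRound(plan, 1)
  cfg <- trainConfig(
    learningRate = 1e-3, batchSize = 15, maxEpochs = 4,
    patience = 4, seed = 19
  )
  model <- buildModel(s$map, s$net, seed = 19)
  fitA <- trainOneRound(s$cohort, rd$train, rd$validation, model, cfg)

  mods <- modalities(s$cohort)
  poisoned <- lapply(mods, function(om) {
    v <- values(om)
    v[rd$test, ] <- 1e6
    OmicsMatrix(v, modalityName(om))
  })
  cohortB <- MultiOmicsCohort(
    poisoned, survivalTable(s$cohort),
    cutoffYears(s$cohort),
    labels = cohortLabels(s$cohort)
  )
  fitB <- trainOneRound(cohortB, rd$train, rd$validation, model, cfg)
  expect_identical(fitA$model$params, fitB$model$params)
})

test_that("the ICLL ablation differs only in constraint layers", {
  s <- smallTrainSetup(n = 60, seed = 55)
  plan <- makeFoldPlan(cohortLabels(s$cohort), seed = 4)
  cfg <- trainConfig(
    learningRate = 1e-3, batchSize = 15, maxEpochs = 3,
    patience = 3, seed = 23
  )
  ab <- runAblationICLL(s$cohort, plan, cfg, s$net, s$map)
  expect_null(ab$full$config$weights$constraintLayers)
  expect_identical(ab$icll$config$weights$constraintLayers, "last")
  cfgOther <- ab$icll$config
  cfgOther$weights$constraintLayers <- NULL
  expect_identical(ab$full$config, cfgOther)
  expect_named(ab$delta, c("acc", "recall", "precision", "auc"))

  # with the constraint weights at zero the two modes coincide
  cfg0 <- cfg
  cfg0$weights <- lossWeights(wDiff = 0, wDiss = 0, wCon = 0.1)
  ab0 <- runAblationICLL(s$cohort, plan, cfg0, s$net, s$map)
  expect_identical(ab0$full$roundScores, ab0$icll$roundScores)
  expect_equal(unname(ab0$delta), rep(0, 4))
})

test_that("training logs every component and writes a CSV", {
  s <- smallTrainSetup()
  cfg <- trainConfig(
    learningRate = 1e-3, batchSize = 10, maxEpochs = 3,
    patience = 3, seed = 1
  )
  fit <- trainOneRound(
    s$cohort, 1:40, 41:50,
    buildModel(s$map, s$net, seed = 1), cfg
  )
  expect_named(
    fit$log,
    c("epoch", "lCE", "lDiff", "lDiss", "lCon", "total", "valTotal")
  )
  expect_true(all(is.finite(as.matrix(fit$log))))
  f <- withr::local_tempfile(fileext = ".csv")
  writeTrainingLog(fit$log, f)
  back <- read.csv(f)
  expect_equal(back$valTotal, fit$log$valTotal)
})
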