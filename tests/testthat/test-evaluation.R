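test_that("confusion counts treat short-survival (label 0) as positive", {
  # 4 shorts all predicted short; 4 longs with one predicted short
  yTrue <- c(0, 0, 0, 0, 1, 1, 1, 1)
  yPred <- c(0, 0, 0, 0, 0, 1, 1, 1)
  cc <- confusionCounts(yTrue, yPred)
  expect_equal(cc$tp, 4)
  expect_equal(cc$fn, 0)
  expect_equal(cc$tn, 3)
  expect_equal(cc$fp, 1)
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 8)

  perfect <- confusionCounts(yTrue, yTrue)
  expect_equal(perfect$fp + perfect$fn, 0)

  allLong <- confusionCounts(yTrue, rep(1, 8))
  expect_equal(allLong$tp, 0)
  expect_equal(allLong$fp, 0)

  expect_error(confusionCounts(yTrue, yPred[-1]), "length")
})

test_that("accuracy, recall and precision follow their defining ratios", {
  m <- classificationMetrics(confusionCounts(
    c(0, 0, 0, 0, 1, 1, 1, 1),
    c(0, 0, 0, 0, 0, 1, 1, 1)
  ))
  expect_equal(m$acc, 0.875)
  expect_equal(m$recall, 1.0)
  expect_equal(m$precision, 0.8)

  perfect <- classificationMetrics(confusionCounts(c(0, 1), c(0, 1)))
  expect_equal(unlist(perfect), c(acc = 1, recall = 1, precision = 1))

  # tp = fp = 0: precision guarded to 0 with a warning
  expect_warning(
    z <- classificationMetrics(confusionCounts(c(0, 0, 1), c(1, 1, 1))),
    "precision"
  )
  expect_equal(z$precision, 0)
  expect_equal(z$recall, 0)

  # round trip: metrics recomputed from reconstructed counts agree
  set.seed(3)
  for (i in 1:10) {
    yT <- rbinom(40, 1, 0.4)
    yP <- rbinom(40, 1, 0.5)
    cc <- confusionCounts(yT, yP)
    m1 <- suppressWarnings(classificationMetrics(cc))
    cc2 <- confusionCounts(yT, yP)
    expect_identical(suppressWarnings(classificationMetrics(cc2)), m1)
  }
})

test_that("ROC/AUC equals exhaustive concordance counting", {
  # worked example: labels (+,-,+,-) by score order -> AUC 0.75
  r <- rocAuc(c(0, 1, 0, 1), c(0.9, 0.8, 0.4, 0.3))
  expect_equal(r$auc, 0.75)
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[1], 0)
  expect_equal(tail(r$roc$fpr, 1), 1)
  expect_equal(tail(r$roc$tpr, 1), 1)

  # perfect separation and a constant scorer
  expect_equal(rocAuc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(rocAuc(c(0, 0, 1, 1), rep(0.5, 4))$auc, 0.5)
  expect_error(rocAuc(c(0, 0), c(0.2, 0.4)), "both classes")

  # random fixtures incl. heavy ties, up to n = 200
  set.seed(9)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    sc <- round(runif(n), sample(c(1, 2, 6), 1))
    r <- rocAuc(y, sc)
    expect_equal(r$auc, aucByPairs(y, sc), tolerance = 1e-12)
    expect_true(all(diff(r$roc$fpr) >= 0))
    expect_true(all(diff(r$roc$tpr) >= 0))
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:5) {
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    sc <- runif(60)
    ours <- rocAuc(y, sc)$auc
    # pROC: response with positive class 0, higher score -> more positive
    ref <- suppressMessages(pROC::auc(
      pROC::roc(y, sc, levels = c(1, 0), direction = "<")
    ))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("log-rank statistic matches the risk-table oracle", {
  # 6-sample worked example, all events observed, groups {1,2,3} vs {4,5,6}
  times <- c(1, 2, 3, 4, 5, 6)
  events <- rep(TRUE, 6)
  groups <- rep(c(0, 1), each = 3)
  km <- kmCurves(times, events, groups)
  expect_equal(km$logrankChi2, logrankByRiskTable(times, events, groups),
    tolerance = 1e-10
  )
  # identical groups (same time/event multiset) give a zero statistic
  t2 <- rep(c(3, 7, 11), 2)
  e2 <- rep(TRUE, 6)
  g2 <- rep(c(0, 1), 3)
  expect_lt(kmCurves(t2, e2, g2)$logrankChi2, 1e-10)

  # no events at all: both curves flat at 1, statistic 0
  km0 <- kmCurves(c(2, 4, 6, 8), rep(FALSE, 4), c(0, 0, 1, 1))
  expect_equal(km0$logrankChi2, 0)
  expect_equal(km0$pValue, 1)
  expect_true(all(unlist(lapply(km0$curves, function(cv) cv$survival)) == 1))

  # random fixtures with censoring, up to n = 50
  set.seed(21)
  for (i in 1:12) {
    n <- sample(10:50, 1)
    tt <- round(rexp(n, 0.05), 1)
    ee <- runif(n) < 0.7
    gg <- rbinom(n, 1, 0.5)
    if (length(unique(gg)) < 2) gg[1:2] <- c(0, 1)
    if (!any(ee)) ee[1] <- TRUE
    km <- kmCurves(tt, ee, gg)
    expect_equal(km$logrankChi2, logrankByRiskTable(tt, ee, gg),
      tolerance = 1e-8
    )
    expect_equal(km$pValue, pchisq(km$logrankChi2, 1, lower.tail = FALSE))
  }
})

test_that("survival curves are valid product-limit estimates", {
  set.seed(5)
  tt <- round(rexp(30, 0.04), 1)
  ee <- runif(30) < 0.8
  gg <- rbinom(30, 1, 0.5)
  gg[1:2] <- c(0, 1)
  if (!any(ee)) ee[1] <- TRUE
  km <- kmCurves(tt, ee, gg)
  for (cv in km$curves) {
    expect_true(all(diff(cv$survival) <= 1e-12))
    expect_true(all(cv$survival >= 0 & cv$survival <= 1))
  }
})

test_that("evalReport combines counts, ratio metrics and ROC", {
  set.seed(8)
  y <- rbinom(50, 1, 0.5)
  y[1:2] <- c(0, 1)
  sc <- ifelse(y == 0, rnorm(50, 0.7, 0.2), rnorm(50, 0.3, 0.2))
  rep <- evalReport(y, sc)
  expect_equal(
    rep$acc,
    (rep$counts$tp + rep$counts$tn) / 50
  )
  expect_gt(rep$auc, 0.5)
  f <- withr::local_tempfile(fileext = ".json")
  writeEvalReport(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$auc, rep$auc)
  expect_equal(back$counts$tp, rep$counts$tp)
})

test_that("ROC points and KM steps export as TSV", {
  set.seed(4)
  y <- rep(c(0, 1), 15)
  sc <- ifelse(y == 0, rnorm(30, 0.6, 0.2), rnorm(30, 0.4, 0.2))
  rep <- evalReport(y, sc)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  writeRocPoints(rep, f1)
  roc <- read.table(f1, header = TRUE)
  expect_equal(roc$fpr, rep$roc$fpr)

  tt <- round(rexp(30, 0.05), 1)
  ee <- runif(30) < 0.8
  if (!any(ee)) ee[1] <- TRUE
  km <- kmCurves(tt, ee, y)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeKmSteps(km, f2)
  steps <- read.table(f2, header = TRUE)
  expect_identical(sort(unique(as.character(steps$group))), sort(names(km$curves)))
})

test_that("embedding export writes labeled 2-D coordinates deterministically", {
  set.seed(2)
  X <- matrix(rnorm(40 * 6), 40)
  labs <- rep(c(0, 1), 20)
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- exportEmbedding(X, labs, f, method = "pca", seed = 7)
  expect_equal(nrow(df), 40)
  hdr <- readLines(f, n = 1)
  expect_match(hdr, "method=pca")
  back <- readEmbedding(f)
  expect_equal(nrow(back), 40)
  expect_equal(back$label, labs)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  df2 <- exportEmbedding(X, labs, f2, method = "pca", seed = 7)
  expect_identical(df, df2)
  expect_error(exportEmbedding(X[1:4, ], labs[1:4], f), "at least 5")
})
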