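#' Confusion counts with short-survival as the positive class
#'
#' By convention the positive class is the short-term survivor, which is
#' encoded by label 0: TP = short correctly identified as short,
#' FP = long identified as short, TN = long as long, FN = short as long.
#'
#' @param yTrue,yPred 0/1 vectors of equal length (0 = short-survival).
#' @param positive the label treated as positive (default `0`).
#' @return a `ConfusionCounts` list with `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusionCounts(c(0, 0, 1, 1), c(0, 1, 1, 0)) # tp 1, fn 1, tn 1, fp 1
#' @export
confusionCounts <- function(yTrue, yPred, positive = 0L) {
  assertThat(length(yTrue) == length(yPred), "length mismatch")
  pos <- yTrue == positive
  posHat <- yPred == positive
  counts <- list(
    tp = sum(pos & posHat), fp = sum(!pos & posHat),
    tn = sum(!pos & !posHat), fn = sum(pos & !posHat)
  )
  class(counts) <- "ConfusionCounts"
  counts
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  cat(sprintf(
    "ConfusionCounts: TP %d  FP %d  TN %d  FN %d\n",
    x$tp, x$fp, x$tn, x$fn
  ))
  invisible(x)
}

#' Accuracy, recall and precision from confusion counts
#'
#' `Acc = (TP+TN)/(TP+TN+FP+FN)`, `Recall = TP/(TP+FN)`,
#' `Pre = TP/(TP+FP)`.  Recall and precision are defined as 0 (with a
#' warning) when their denominator is zero.
#'
#' @param counts a [confusionCounts()] result.
#' @return list with `acc`, `recall`, `precision`.
#' @examples
#' classificationMetrics(confusionCounts(
#'   c(0, 0, 0, 0, 1, 1, 1, 1),
#'   c(0, 0, 0, 0, 0, 1, 1, 1)
#' )) # acc 0.875, recall 1, precision 0.8
#' @export
classificationMetrics <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  assertThat(total > 0, "empty confusion counts")
  safeDiv <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); returning 0")
      0
    } else {
      num / den
    }
  }
  list(
    acc = (counts$tp + counts$tn) / total,
    recall = safeDiv(counts$tp, counts$tp + counts$fn, "recall"),
    precision = safeDiv(counts$tp, counts$tp + counts$fp, "precision")
  )
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score threshold (ties grouped), predicting
#' positive when `score >= threshold`, and integrates the resulting
#' (FPR, TPR) staircase by the trapezoidal rule.  The AUC equals the
#' Mann-Whitney concordance probability (ties counted half).
#'
#' @param yTrue 0/1 labels; both classes must be present.
#' @param scores numeric scores, higher = more likely positive.
#' @param positive label treated as positive (default `0`,
#'   short-survival).
#' @return list with `roc` (data.frame `fpr`, `tpr`, starting at (0,0)
#'   and ending at (1,1)) and `auc`.
#' @examples
#' rocAuc(c(0, 1, 0, 1), c(0.9, 0.8, 0.4, 0.3))$auc # 0.75
#' @export
rocAuc <- function(yTrue, scores, positive = 0L) {
  pos <- yTrue == positive
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  assertThat(
    nPos > 0 && nNeg > 0,
    "ROC undefined: both classes must be present"
  )
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  ## cumulative counts at each distinct threshold (ties grouped)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(p)[last] / nPos
  fpr <- cumsum(!p)[last] / nNeg
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(roc = roc, auc = auc)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimate per risk group (high risk = predicted
#' short-term) with the 1-df log-rank statistic and its chi-square
#' p-value; delegates the estimates to the survival package.  Groups with
#' no events yield a curve flat at 1.  When no event occurs at all, the
#' statistic is 0 and p = 1.
#'
#' @param times survival in months.
#' @param events logical/0-1, TRUE = death observed.
#' @param groups binary risk assignment (e.g. predicted class).
#' @return a `KMResult` list: per-group `curves` (data.frame time,
#'   survival, nRisk, nEvent), `medianSurvival` per group, `logrankChi2`,
#'   `pValue`.
#' @export
kmCurves <- function(times, events, groups) {
  events <- as.logical(events)
  groups <- as.factor(groups)
  assertThat(
    nlevels(groups) == 2L && all(table(groups) >= 1L),
    "exactly two non-empty groups required"
  )
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  sm <- summary(fit, censored = TRUE)
  strat <- if (is.null(sm$strata)) {
    factor(rep(levels(groups)[1L], length(sm$time)))
  } else {
    sm$strata
  }
  curves <- lapply(seq_len(nlevels(strat)), function(i) {
    sel <- as.integer(strat) == i
    data.frame(
      time = sm$time[sel], survival = sm$surv[sel],
      nRisk = sm$n.risk[sel], nEvent = sm$n.event[sel]
    )
  })
  names(curves) <- sub("^groups=", "", levels(strat))
  med <- summary(fit)$table
  medianSurvival <- if (is.matrix(med)) {
    stats::setNames(med[, "median"], sub("^groups=", "", rownames(med)))
  } else {
    stats::setNames(med[["median"]], levels(groups)[1L])
  }
  if (!any(events)) {
    chi2 <- 0
    p <- 1
  } else {
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
    chi2 <- sd$chisq
    p <- pchisq(chi2, df = 1L, lower.tail = FALSE)
  }
  out <- list(
    curves = curves, medianSurvival = medianSurvival,
    logrankChi2 = chi2, pValue = p
  )
  class(out) <- "KMResult"
  out
}

#' @export
print.KMResult <- function(x, ...) {
  cat(sprintf(
    "KMResult: %d groups, log-rank chi2 %.4g, p = %.3g\n",
    length(x$curves), x$logrankChi2, x$pValue
  ))
  invisible(x)
}

#' Full evaluation report for scored samples
#'
#' Combines confusion counts at the score threshold, the ratio-style
#' accuracy/recall/precision, and the ROC/AUC.
#'
#' @param yTrue 0/1 labels.
#' @param scores short-class probabilities.
#' @param threshold predicted-short threshold on the score (default 0.5).
#' @return an `EvalReport` list: `counts`, `acc`, `recall`, `precision`,
#'   `roc`, `auc`.
#' @export
evalReport <- function(yTrue, scores, threshold = 0.5) {
  yPred <- ifelse(scores >= threshold, 0L, 1L)
  counts <- confusionCounts(yTrue, yPred)
  metrics <- classificationMetrics(counts)
  roc <- rocAuc(yTrue, scores)
  out <- c(list(counts = counts), metrics, roc)
  class(out) <- "EvalReport"
  out
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf(
    "EvalReport: Acc %.3f, Recall %.3f, Pre %.3f, AUC %.3f (TP %d FP %d TN %d FN %d)\n",
    x$acc, x$recall, x$precision, x$auc,
    x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn
  ))
  invisible(x)
}

#' Write ROC points or Kaplan-Meier step functions as TSV
#'
#' @param report an `EvalReport` (for `writeRocPoints`) or `KMResult`
#'   (for `writeKmSteps`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeRocPoints <- function(report, path) {
  write.table(report$roc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRocPoints
#' @export
writeKmSteps <- function(report, path) {
  steps <- do.call(rbind, lapply(names(report$curves), function(g) {
    cbind(group = g, report$curves[[g]])
  }))
  write.table(steps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize an EvalReport or KMResult to JSON / TSV
#'
#' @param report an `EvalReport` or `KMResult`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  obj <- unclass(report)
  if (!is.null(obj$counts)) obj$counts <- unclass(obj$counts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
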