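#' Loss weights and constraint configuration
#'
#' The total objective is the weighted sum
#' `wCE * L_ce + wDiff * L_diff + wDiss * L_diss + wCon * L_con` of
#' cross-entropy, layer-wise orthogonality, layer-wise cross-modality
#' Euclidean distance and margin contrastive losses.  `constraintLayers`
#' selects which branch layers the orthogonality/distance terms act on:
#' `NULL` (default) means every layer ("layer-by-layer"); the ICLL
#' ablation restricts them to the last layer.
#'
#' Cross-entropy keeps weight 1 so classification stays the dominant
#' objective; the auxiliary terms default to 0.1 each.
#'
#' @param wCE,wDiff,wDiss,wCon non-negative weights.
#' @param margin contrastive margin (> 0, default 2.0).
#' @param constraintLayers integer vector of branch-layer indices, or
#'   `NULL` for all layers, or `"last"` for the ICLL mode.
#' @return a `lossWeights` list.
#' @export
lossWeights <- function(wCE = 1, wDiff = 0.1, wDiss = 0.1, wCon = 0.1,
                        margin = 2.0, constraintLayers = NULL) {
  assertThat(
    all(c(wCE, wDiff, wDiss, wCon) >= 0),
    "loss weights must be >= 0"
  )
  assertThat(margin > 0, "margin must be > 0")
  w <- list(
    wCE = wCE, wDiff = wDiff, wDiss = wDiss, wCon = wCon,
    margin = margin, constraintLayers = constraintLayers
  )
  class(w) <- "lossWeights"
  w
}

resolveConstraintLayers <- function(weights, nLayers) {
  cl <- weights$constraintLayers
  if (is.null(cl)) {
    return(seq_len(nLayers))
  }
  if (identical(cl, "last")) {
    return(nLayers)
  }
  cl <- as.integer(cl)
  assertThat(all(cl >= 1L & cl <= nLayers), "constraintLayers out of range")
  cl
}

#' Orthogonality (difference) loss
#'
#' Squared Frobenius norm of the cross-product of the shared and specific
#' activations of one modality at one layer, `||Hc' Hs||_F^2`, optionally
#' divided by the squared batch size so the term's scale does not depend
#' on the batch (the published batch size is fixed at 30, where the two
#' conventions differ only by a constant).
#'
#' @param Hc,Hs batch x d matrices (same shape).
#' @param normalize divide by `nrow(Hc)^2` (default TRUE).
#' @param grad also return gradients.
#' @return the loss, or (with `grad = TRUE`) `list(value, gHc, gHs)`.
#' @examples
#' orthogonalityLoss(diag(2), diag(2), normalize = FALSE) # 2
#' @export
orthogonalityLoss <- function(Hc, Hs, normalize = TRUE, grad = FALSE) {
  assertThat(
    all(dim(Hc) == dim(Hs)),
    "Hc and Hs must have the same shape"
  )
  M <- crossprod(Hc, Hs)
  scale <- if (normalize) 1 / nrow(Hc)^2 else 1
  value <- sum(M * M) * scale
  if (!grad) {
    return(value)
  }
  list(
    value = value,
    gHc = 2 * scale * tcrossprod(Hs, M),
    gHs = 2 * scale * (Hc %*% M)
  )
}

#' Cross-modality Euclidean distance (dissimilarity) loss
#'
#' For every unordered modality pair (k, l), computes
#' `(1/2N) * sum_n ||h_k,n - h_l,n||^2` over the batch, then averages over
#' pairs (so changing K does not rescale the term).
#'
#' @param sharedList list of >= 1 batch x d matrices, one per modality.
#' @param grad also return gradients (list parallel to `sharedList`).
#' @return the loss, or `list(value, gList)`.
#' @examples
#' distanceLoss(list(matrix(0, 1, 2), matrix(c(3, 4), 1))) # 12.5
#' @export
distanceLoss <- function(sharedList, grad = FALSE) {
  K <- length(sharedList)
  if (K < 2L) {
    warning("distance loss needs >= 2 modalities; returning 0")
    out <- 0
    if (grad) out <- list(value = 0, gList = lapply(sharedList, function(h) h * 0))
    return(out)
  }
  N <- nrow(sharedList[[1L]])
  nPairs <- K * (K - 1L) / 2
  value <- 0
  for (k in seq_len(K - 1L)) {
    for (l in seq((k + 1L), K)) {
      diff <- sharedList[[k]] - sharedList[[l]]
      value <- value + sum(diff * diff) / (2 * N)
    }
  }
  value <- value / nPairs
  if (!grad) {
    return(value)
  }
  ## d/dh_k of the pair mean: (1/(N * nPairs)) * sum_{l != k} (h_k - h_l)
  sumAll <- Reduce(`+`, sharedList)
  gList <- lapply(sharedList, function(h) {
    (K * h - sumAll) / (N * nPairs)
  })
  list(value = value, gList = gList)
}

#' Euclidean distance between two fused representations
#'
#' @param hi,hj numeric vectors of equal length.
#' @return `||hi - hj||_2`.
#' @export
pairwiseDistance <- function(hi, hj) {
  assertThat(length(hi) == length(hj), "vectors must have equal length")
  sqrt(sum((hi - hj)^2))
}

#' Margin contrastive loss over labelled pairs
#'
#' `(1/2N) * sum_n [ y_n d_n^2 + (1 - y_n) max(Margin - d_n, 0)^2 ]` over
#' N pairs, with `y_n = 1` for same-class pairs (pulled together) and
#' `y_n = 0` for different-class pairs (pushed apart up to the margin).
#'
#' @param d non-negative pair distances.
#' @param y binary same-class indicators (1 = same class).
#' @param margin positive margin (default 2.0, the published selection).
#' @param grad also return `dLoss/dd`.
#' @return the loss, or `list(value, gd)`.  Empty input gives 0.
#' @examples
#' contrastiveLoss(c(1, 1), c(1, 0), margin = 2) # 0.5
#' @export
contrastiveLoss <- function(d, y, margin = 2.0, grad = FALSE) {
  assertThat(margin > 0, "margin must be > 0")
  n <- length(d)
  if (n == 0L) {
    return(if (grad) list(value = 0, gd = numeric(0)) else 0)
  }
  assertThat(length(y) == n, "d and y must have equal length")
  hinge <- pmax(margin - d, 0)
  value <- sum(y * d^2 + (1 - y) * hinge^2) / (2 * n)
  if (!grad) {
    return(value)
  }
  list(value = value, gd = (y * d - (1 - y) * hinge) / n)
}

#' Cross-entropy loss over softmax logits
#'
#' @param logits batch x 2 matrix of unnormalized class scores
#'   (columns: short, long).
#' @param labels 0/1 vector (0 = short, column 1).
#' @param grad also return the gradient w.r.t. the logits.
#' @return mean negative log-likelihood, or `list(value, gLogits)`.
#' @export
crossEntropyLoss <- function(logits, labels, grad = FALSE) {
  n <- nrow(logits)
  assertThat(length(labels) == n, "labels must match batch size")
  p <- softmaxRows(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  value <- -mean(log(pmax(p[idx], 1e-300)))
  if (!grad) {
    return(value)
  }
  onehot <- matrix(0, n, ncol(logits))
  onehot[idx] <- 1
  list(value = value, gLogits = (p - onehot) / n)
}

#' Combine loss components into a LossReport
#'
#' @param lCE,lDiff,lDiss,lCon component values (each already aggregated
#'   over constraint layers where applicable).
#' @param weights a [lossWeights()].
#' @return a `LossReport` list with the components and the weighted
#'   `total`.
#' @export
totalLoss <- function(lCE, lDiff, lDiss, lCon, weights) {
  stopifnot(inherits(weights, "lossWeights"))
  report <- list(
    lCE = lCE, lDiff = lDiff, lDiss = lDiss, lCon = lCon,
    total = weights$wCE * lCE + weights$wDiff * lDiff +
      weights$wDiss * lDiss + weights$wCon * lCon
  )
  class(report) <- "LossReport"
  report
}

#' @export
print.LossReport <- function(x, ...) {
  cat(sprintf(
    "LossReport: total %.5g (ce %.5g, diff %.5g, diss %.5g, con %.5g)\n",
    x$total, x$lCE, x$lDiff, x$lDiss, x$lCon
  ))
  invisible(x)
}

## All unordered within-batch pairs as index vectors (i < j).
batchPairs <- function(n) {
  if (n < 2L) {
    return(list(i = integer(0), j = integer(0)))
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = idx[, 1L], j = idx[, 2L])
}

## Contrastive loss on a fused batch + gradient w.r.t. the fused matrix.
contrastiveOnFused <- function(fused, labels, margin, grad = FALSE) {
  n <- nrow(fused)
  pr <- batchPairs(n)
  if (!length(pr$i)) {
    return(if (grad) {
      list(value = 0, gFused = fused * 0)
    } else {
      0
    })
  }
  D <- as.matrix(dist(fused))
  d <- D[cbind(pr$i, pr$j)]
  y <- as.numeric(labels[pr$i] == labels[pr$j])
  cl <- contrastiveLoss(d, y, margin, grad = grad)
  if (!grad) {
    return(cl)
  }
  ## dL/dh_i = sum_j c_ij (h_i - h_j), c symmetric, c_ij = gd_ij / d_ij
  C <- matrix(0, n, n)
  safe <- d > 1e-12
  cij <- ifelse(safe, cl$gd / pmax(d, 1e-12), 0)
  C[cbind(pr$i, pr$j)] <- cij
  C <- C + t(C)
  gFused <- rowSums(C) * fused - C %*% fused
  list(value = cl$value, gFused = gFused)
}
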