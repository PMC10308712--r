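## Full objective and its gradient for one batch.
##
## Aggregation conventions (fixed; see the methods vignette):
##  * L_diff: per constraint layer, mean over modalities of the
##    batch-normalized orthogonality loss; summed over constraint layers.
##  * L_diss: per constraint layer, mean over unordered modality pairs of
##    (1/2N) sum_n ||h_k - h_l||^2; summed over constraint layers.
##  * L_con: all unordered within-batch pairs on the fused representation.
##  * L_ce: mean softmax cross-entropy.

#' Evaluate the training objective on a batch
#'
#' Computes the four loss components and (optionally) the gradient of the
#' weighted total with respect to every model parameter, by explicit
#' backpropagation with the layer-by-layer constraint gradients injected
#' at each constrained branch layer.
#'
#' @param model an `ssnModel`.
#' @param xs list of K batch x q_k matrices.
#' @param labels 0/1 vector for the batch.
#' @param weights a [lossWeights()].
#' @param grad return gradients as well.
#' @return `list(report, bundle)` or `list(report, bundle, grads)` with
#'   `grads` mirroring `model$params`.
#' @export
modelLoss <- function(model, xs, labels, weights, grad = FALSE) {
  K <- model$K
  bundle <- forwardModel(model, xs)
  L <- model$nBranchLayers
  layers <- resolveConstraintLayers(weights, L)
  N <- nrow(bundle$fused)

  ## ---- loss components ----
  ceR <- crossEntropyLoss(bundle$logits, labels, grad = grad)
  conR <- contrastiveOnFused(bundle$fused, labels, weights$margin, grad = grad)

  orthoR <- vector("list", L) # [[m]][[k]] grads
  lDiff <- 0
  dissR <- vector("list", L)
  lDiss <- 0
  for (m in layers) {
    om <- lapply(seq_len(K), function(k) {
      orthogonalityLoss(bundle$sharedActs[[k]][[m]],
        bundle$specificActs[[k]][[m]],
        normalize = TRUE, grad = grad
      )
    })
    if (grad) {
      lDiff <- lDiff + mean(vapply(om, `[[`, 0, "value"))
    } else {
      lDiff <- lDiff + mean(unlist(om))
    }
    orthoR[[m]] <- om
    dm <- if (K >= 2L) {
      distanceLoss(
        lapply(seq_len(K), function(k) bundle$sharedActs[[k]][[m]]),
        grad = grad
      )
    } else {
      ## single modality: the cross-modality term vanishes
      list(value = 0, gList = list(bundle$sharedActs[[1L]][[m]] * 0))
    }
    lDiss <- lDiss + if (grad) dm$value else if (K >= 2L) dm else 0
    dissR[[m]] <- dm
  }
  lCon <- if (grad) conR$value else conR
  lCE <- if (grad) ceR$value else ceR
  report <- totalLoss(lCE, lDiff, lDiss, lCon, weights)
  if (!grad) {
    return(list(report = report, bundle = bundle))
  }

  ## ---- backward ----
  ## classifier
  gLogits <- weights$wCE * ceR$gLogits
  clsBack <- stackBackward(
    model$params$classifier, bundle$fused,
    bundle$clsActs, gLogits
  )
  gFused <- clsBack$gX + weights$wCon * conR$gFused

  ## split fused gradient: K specific blocks then averaged-shared block
  E <- model$net$embedSize
  gSpecificTop <- lapply(seq_len(K), function(k) {
    gFused[, ((k - 1L) * E + 1L):(k * E), drop = FALSE]
  })
  gHC <- gFused[, (K * E + 1L):((K + 1L) * E), drop = FALSE]

  gradMapTop <- vector("list", K) # accumulated grad at mapping output
  gShared <- if (model$tieSharedWeights) NULL else vector("list", K)
  gSpecific <- vector("list", K)
  for (k in seq_len(K)) {
    ## constraint gradients injected per layer
    extraShared <- vector("list", L)
    extraSpecific <- vector("list", L)
    for (m in layers) {
      extraShared[[m]] <- weights$wDiff / K * orthoR[[m]][[k]]$gHc +
        weights$wDiss * dissR[[m]]$gList[[k]]
      extraSpecific[[m]] <- weights$wDiff / K * orthoR[[m]][[k]]$gHs
    }
    mapped <- bundle$mapActs[[k]][[length(bundle$mapActs[[k]])]]
    sb <- stackBackward(
      sharedStackOf(model, k), mapped, bundle$sharedActs[[k]],
      gHC / K, extraShared
    )
    pb <- stackBackward(
      model$params$specific[[k]], mapped, bundle$specificActs[[k]],
      gSpecificTop[[k]], extraSpecific
    )
    if (model$tieSharedWeights) {
      gShared <- treeAdd(gShared, list(gW = sb$gW, gb = sb$gb))
    } else {
      gShared[[k]] <- list(gW = sb$gW, gb = sb$gb)
    }
    gSpecific[[k]] <- list(gW = pb$gW, gb = pb$gb)
    gradMapTop[[k]] <- sb$gX + pb$gX
  }
  gMapping <- lapply(seq_len(K), function(k) {
    mb <- stackBackward(
      model$params$mapping[[k]], xs[[k]],
      bundle$mapActs[[k]], gradMapTop[[k]]
    )
    list(gW = mb$gW, gb = mb$gb)
  })

  asParamTree <- function(g) list(W = g$gW, b = g$gb)
  grads <- list(
    mapping = lapply(gMapping, asParamTree),
    shared = if (model$tieSharedWeights) {
      list(asParamTree(gShared))
    } else {
      lapply(gShared, asParamTree)
    },
    specific = lapply(gSpecific, asParamTree),
    classifier = list(W = clsBack$gW, b = clsBack$gb)
  )
  list(report = report, bundle = bundle, grads = grads)
}
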