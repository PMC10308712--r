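#' Feature-mapping specification
#'
#' Every modality is mapped by a three-layer fully connected stack
#' `q_k -> hidden_k -> outputDim` to a common dimension before the shared
#' and specific branches.  Dimensionality is only reduced, never increased:
#' by default the common output dimension is the smallest modality input
#' dimension (for mRNA/miRNA/methylation panels this is the miRNA dimension,
#' which is too low to reduce further), and the default hidden width is the
#' geometric mean of input and output capped at 512.
#'
#' @param inputDims K positive feature dimensions, one per modality.
#' @param outputDim common mapped dimension (default `min(inputDims)`).
#' @param hiddenDims K hidden widths (default geometric-mean rule).
#' @return a `mappingSpec` list with `inputDims`, `hiddenDims`, `outputDim`.
#' @examples
#' mappingSpec(c(12042, 534, 1305), hiddenDims = c(4096, 534, 768))
#' @export
mappingSpec <- function(inputDims, outputDim = NULL, hiddenDims = NULL) {
  inputDims <- stats::setNames(as.integer(inputDims), names(inputDims))
  assertThat(all(inputDims >= 1L), "inputDims must be positive")
  if (is.null(outputDim)) outputDim <- min(inputDims)
  outputDim <- as.integer(outputDim)
  if (is.null(hiddenDims)) {
    hiddenDims <- pmin(512L, pmax(outputDim, round(sqrt(inputDims * outputDim))))
  }
  hiddenDims <- as.integer(rep_len(hiddenDims, length(inputDims)))
  spec <- list(
    inputDims = inputDims, hiddenDims = hiddenDims,
    outputDim = outputDim
  )
  class(spec) <- "mappingSpec"
  spec
}

#' @export
print.mappingSpec <- function(x, ...) {
  cat("mappingSpec:\n")
  for (k in seq_along(x$inputDims)) {
    cat(
      "  modality", k, ":", x$inputDims[k], "->", x$hiddenDims[k], "->",
      x$outputDim, "\n"
    )
  }
  invisible(x)
}

#' Network configuration for the branch and classifier stacks
#'
#' The shared and specific branch networks use identical layer widths —
#' required so the layer-wise orthogonality product and the fused-dimension
#' arithmetic are well formed.  Every mapping and branch layer uses the
#' rectifier activation; the classifier has one rectified hidden layer and
#' linear logits over the two survival classes.
#'
#' @param hiddenSizes branch hidden widths (default `c(256, 128)`).
#' @param embedSize branch output (embedding) width (default 32).
#' @param classifierHidden classifier hidden width (default 32).
#' @param nClasses number of classes (2).
#' @return a `netConfig` list.
#' @export
netConfig <- function(hiddenSizes = c(256L, 128L), embedSize = 32L,
                      classifierHidden = 32L, nClasses = 2L) {
  cfg <- list(
    hiddenSizes = as.integer(hiddenSizes),
    embedSize = as.integer(embedSize),
    classifierHidden = as.integer(classifierHidden),
    nClasses = as.integer(nClasses)
  )
  assertThat(all(unlist(cfg) >= 1L), "all sizes must be positive")
  class(cfg) <- "netConfig"
  cfg
}

#' Build the multi-stream shared/specific model
#'
#' Constructs, with seeded He initialization: K feature-mapping stacks, K
#' shared-branch stacks, K specific-branch stacks (shared and specific
#' branches have identical widths `hiddenSizes -> embedSize`), and the
#' classifier over the fused representation of width
#' `K * embedSize + embedSize`.
#'
#' By default each modality has its own shared-branch parameters, tied
#' across modalities only through the Euclidean distance penalty;
#' `tieSharedWeights = TRUE` instead hard-shares one parameter set across
#' all modalities.
#'
#' @param mapping a [mappingSpec()].
#' @param net a [netConfig()].
#' @param seed integer seed for initialization.
#' @param tieSharedWeights hard-share the shared branch across modalities.
#' @param bias include bias terms (default TRUE; disable for linear-algebra
#'   unit checks).
#' @return an `ssnModel` list (weights under `$params`).
#' @examples
#' m <- buildModel(mappingSpec(c(30, 10, 20)),
#'   netConfig(hiddenSizes = c(16, 8), embedSize = 4),
#'   seed = 1
#' )
#' m$fusedDim
#' @export
buildModel <- function(mapping, net = netConfig(), seed = 1L,
                       tieSharedWeights = FALSE, bias = TRUE) {
  stopifnot(inherits(mapping, "mappingSpec"), inherits(net, "netConfig"))
  K <- length(mapping$inputDims)
  branchSizes <- c(mapping$outputDim, net$hiddenSizes, net$embedSize)
  fusedDim <- K * net$embedSize + net$embedSize
  params <- withSeed(seed, {
    list(
      mapping = lapply(seq_len(K), function(k) {
        makeStack(
          c(mapping$inputDims[k], mapping$hiddenDims[k], mapping$outputDim),
          "relu", bias
        )
      }),
      shared = lapply(seq_len(if (tieSharedWeights) 1L else K), function(k) {
        makeStack(branchSizes, "relu", bias)
      }),
      specific = lapply(seq_len(K), function(k) {
        makeStack(branchSizes, "relu", bias)
      }),
      classifier = makeStack(
        c(fusedDim, net$classifierHidden, net$nClasses),
        c("relu", "identity"), bias
      )
    )
  })
  model <- list(
    K = K, mapping = mapping, net = net, params = params,
    tieSharedWeights = tieSharedWeights, bias = bias,
    fusedDim = fusedDim, nBranchLayers = length(branchSizes) - 1L,
    seed = as.integer(seed)
  )
  class(model) <- "ssnModel"
  model
}

#' @export
print.ssnModel <- function(x, ...) {
  cat("ssnModel: K=", x$K, ", mapped dim ", x$mapping$outputDim,
    ", branches ", paste(c(x$net$hiddenSizes, x$net$embedSize),
      collapse = "-"
    ),
    ", fused dim ", x$fusedDim,
    if (x$tieSharedWeights) ", tied shared weights" else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

sharedStackOf <- function(model, k) {
  if (model$tieSharedWeights) {
    model$params$shared[[1L]]
  } else {
    model$params$shared[[k]]
  }
}

#' Forward pass through the model
#'
#' Runs all K modalities through mapping, shared and specific branches and
#' the classifier, returning every per-layer activation of both branches
#' (the layer-by-layer objectives need them), the final embeddings, the
#' averaged shared embedding, the fused vector and the class scores.
#'
#' @param model an `ssnModel` from [buildModel()].
#' @param xs list of K numeric matrices (batch x q_k), same sample order.
#' @return a `RepresentationBundle` list: `mapActs`, `sharedActs`,
#'   `specificActs` (per modality, per layer), `hSpecific`, `hShared`
#'   (final embeddings), `hC` (averaged shared), `fused`, `clsActs`,
#'   `logits`, `probs` (columns: short, long), `scoreShort`.
#' @export
forwardModel <- function(model, xs) {
  assertThat(
    length(xs) == model$K,
    sprintf("expected %d modalities, got %d", model$K, length(xs))
  )
  for (k in seq_len(model$K)) {
    assertThat(
      ncol(xs[[k]]) == model$mapping$inputDims[k],
      sprintf(
        "modality %d: %d features, expected %d", k, ncol(xs[[k]]),
        model$mapping$inputDims[k]
      )
    )
  }
  K <- model$K
  mapActs <- vector("list", K)
  sharedActs <- vector("list", K)
  specificActs <- vector("list", K)
  for (k in seq_len(K)) {
    mapActs[[k]] <- stackForward(model$params$mapping[[k]], xs[[k]])
    mapped <- mapActs[[k]][[length(mapActs[[k]])]]
    sharedActs[[k]] <- stackForward(sharedStackOf(model, k), mapped)
    specificActs[[k]] <- stackForward(model$params$specific[[k]], mapped)
  }
  L <- model$nBranchLayers
  hShared <- lapply(sharedActs, function(a) a[[L]])
  hSpecific <- lapply(specificActs, function(a) a[[L]])
  hC <- Reduce(`+`, hShared) / K
  fused <- do.call(cbind, c(hSpecific, list(hC)))
  clsActs <- stackForward(model$params$classifier, fused)
  logits <- clsActs[[length(clsActs)]]
  probs <- softmaxRows(logits)
  colnames(probs) <- c("short", "long")
  bundle <- list(
    xs = xs, mapActs = mapActs, sharedActs = sharedActs,
    specificActs = specificActs, hShared = hShared,
    hSpecific = hSpecific, hC = hC, fused = fused,
    clsActs = clsActs, logits = logits, probs = probs,
    scoreShort = probs[, "short"]
  )
  class(bundle) <- "RepresentationBundle"
  bundle
}

#' Fuse a representation bundle
#'
#' Concatenates the modality-specific embeddings (in modality order) with
#' the averaged shared embedding: `h = [h_1^s, ..., h_K^s, h^c]` where
#' `h^c` is the arithmetic mean of the per-modality shared embeddings.
#' Pure function of the bundle; [forwardModel()] uses the same code path,
#' so the fused vector used for classification and for the contrastive
#' distance is identical by construction.
#'
#' @param bundle a `RepresentationBundle`, or any list with `hSpecific`
#'   (list of matrices) and either `hC` or `hShared`.
#' @return the fused matrix (batch x (K+1) * embedSize).
#' @export
fuseBundle <- function(bundle) {
  hC <- bundle$hC
  if (is.null(hC)) {
    hC <- Reduce(`+`, bundle$hShared) / length(bundle$hShared)
  }
  do.call(cbind, c(bundle$hSpecific, list(hC)))
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Mapping presets for the four published cohorts
#'
#' Returns the feature-mapping dimensions used for the GBM, KRCCC, LSCC
#' and BIC mRNA/miRNA/methylation cohorts (e.g. GBM: 12042->4096->534,
#' 534->534->534, 1305->768->534), together with each cohort's sample
#' count, dichotomization cut-off and short/long class sizes.
#'
#' @param name one of `"gbm"`, `"krccc"`, `"lscc"`, `"bic"`.
#' @return list with `mapping` (a [mappingSpec()]), `cutoffYears`,
#'   `nSamples`, `classCounts` (short, long) and `modalities`.
#' @export
datasetPreset <- function(name = c("gbm", "krccc", "lscc", "bic")) {
  name <- match.arg(name)
  tab <- list(
    gbm = list(
      dims = c(mRNA = 12042L, miRNA = 534L, DNAmeth = 1305L),
      hidden = c(4096L, 534L, 768L), out = 534L,
      cutoff = 2, n = 215L, classes = c(short = 166L, long = 49L)
    ),
    krccc = list(
      dims = c(mRNA = 17899L, miRNA = 329L, DNAmeth = 24960L),
      hidden = c(4096L, 329L, 4096L), out = 329L,
      cutoff = 4, n = 122L, classes = c(short = 67L, long = 55L)
    ),
    lscc = list(
      dims = c(mRNA = 12042L, miRNA = 352L, DNAmeth = 23074L),
      hidden = c(4096L, 352L, 4096L), out = 352L,
      cutoff = 2, n = 106L, classes = c(short = 66L, long = 40L)
    ),
    bic = list(
      dims = c(mRNA = 17814L, miRNA = 354L, DNAmeth = 23094L),
      hidden = c(4096L, 354L, 4096L), out = 354L,
      cutoff = 3, n = 105L, classes = c(short = 67L, long = 38L)
    )
  )[[name]]
  list(
    mapping = mappingSpec(tab$dims,
      outputDim = tab$out,
      hiddenDims = tab$hidden
    ),
    cutoffYears = tab$cutoff, nSamples = tab$n,
    classCounts = tab$classes, modalities = names(tab$dims)
  )
}
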