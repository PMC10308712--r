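#' Build the stratified ten-fold rotation plan
#'
#' Short- and long-term survivors are each randomly partitioned into
#' `nFolds` near-equal subsets (seeded).  Round r (r = 1..nFolds) uses
#' subset r of each class for validation, the next seven subsets
#' (cyclically) for training and the remaining two for testing, so across
#' the ten rounds every subset serves once for validation, seven times for
#' training and twice for testing.
#'
#' @param labels integer 0/1 vector over the cohort samples.
#' @param seed integer seed for the per-class shuffles.
#' @param nFolds number of subsets per class (default 10).
#' @param nTrain,nTest subsets per round used for training / testing
#'   (defaults 7 and 2; with validation they must sum to `nFolds`).
#' @return a [FoldPlan-class].
#' @examples
#' plan <- makeFoldPlan(rep(c(0, 1), each = 20), seed = 1)
#' lengths(foldRound(plan, 1))
#' @export
makeFoldPlan <- function(labels, seed, nFolds = 10L, nTrain = 7L, nTest = 2L) {
  labels <- as.integer(labels)
  assertThat(isBinary(labels), "labels must be 0/1")
  assertThat(
    1L + nTrain + nTest == nFolds,
    "validation + train + test subsets must cover all folds"
  )
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < nFolds)) {
    stop(
      "each class needs at least ", nFolds, " samples; got ",
      paste(counts, collapse = "/"), call. = FALSE
    )
  }
  subsets <- withSeed(seed, {
    lapply(c("0" = 0L, "1" = 1L), function(cls) {
      idx <- sample(which(labels == cls))
      split(idx, rep(seq_len(nFolds), length.out = length(idx)))
    })
  })
  rounds <- lapply(seq_len(nFolds), function(r) {
    rot <- function(offsets) ((r - 1L + offsets) %% nFolds) + 1L
    pick <- function(folds) {
      sort(unlist(lapply(subsets, function(parts) unlist(parts[folds])),
        use.names = FALSE
      ))
    }
    list(
      validation = pick(rot(0L)),
      train = pick(rot(seq_len(nTrain))),
      test = pick(rot(nTrain + seq_len(nTest)))
    )
  })
  new("FoldPlan",
    nFolds = as.integer(nFolds), subsets = subsets,
    rounds = rounds, seed = as.integer(seed)
  )
}

#' Serialize / deserialize a FoldPlan as JSON
#'
#' @param plan a [FoldPlan-class].
#' @param path JSON file path.
#' @return `writeFoldPlan` returns `path` invisibly; `readFoldPlan` the
#'   reconstructed [FoldPlan-class].
#' @export
writeFoldPlan <- function(plan, path) {
  obj <- list(
    nFolds = plan@nFolds, seed = plan@seed,
    subsets = lapply(plan@subsets, function(p) unname(lapply(p, as.integer))),
    rounds = plan@rounds
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFoldPlan
#' @export
readFoldPlan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  subsets <- lapply(obj$subsets, function(p) {
    lapply(p, function(v) as.integer(unlist(v)))
  })
  rounds <- lapply(obj$rounds, function(rd) {
    lapply(rd, function(v) as.integer(unlist(v)))
  })
  new("FoldPlan",
    nFolds = as.integer(obj$nFolds), subsets = subsets,
    rounds = rounds, seed = as.integer(obj$seed)
  )
}
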