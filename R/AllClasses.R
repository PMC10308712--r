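#' OmicsMatrix: one modality's sample-by-feature matrix
#'
#' Stores a single genomic modality (e.g. mRNA expression) as a numeric
#' matrix with samples as rows and features as columns.  Row and column
#' names carry the sample and feature identifiers and must be unique.
#' Missing entries are `NA`.
#'
#' @slot modality single character label, e.g. `"mRNA"`.
#' @slot values numeric matrix, samples x features, dimnames set.
#' @export
setClass("OmicsMatrix",
  representation(modality = "character", values = "matrix"),
  validity = function(object) {
    v <- object@values
    msgs <- character()
    if (length(object@modality) != 1L || is.na(object@modality)) {
      msgs <- c(msgs, "modality must be a single non-NA string")
    }
    if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
    if (is.null(rownames(v)) || is.null(colnames(v))) {
      msgs <- c(msgs, "values must have sample (row) and feature (col) names")
    } else {
      if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicated sample ids")
      if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicated feature ids")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, samples as rows (unless already oriented),
#'   with sample ids as rownames and feature ids as colnames.
#' @param modality character label for the data type.
#' @return an [OmicsMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'   dimnames = list(paste0("s", 1:3), c("g1", "g2")))
#' om <- OmicsMatrix(m, "mRNA")
#' dim(values(om))
#' @export
OmicsMatrix <- function(values, modality = "omics") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("OmicsMatrix", modality = as.character(modality), values = values)
}

#' @describeIn OmicsMatrix number of samples and features
#' @param x,object an OmicsMatrix
#' @export
setMethod("dim", "OmicsMatrix", function(x) dim(x@values))

#' Accessors for OmicsMatrix
#'
#' `values()` returns the numeric matrix, `modalityName()` the label,
#' `sampleIDs()`/`featureIDs()` the identifiers.
#'
#' @param object an [OmicsMatrix-class] (or, for `sampleIDs`, a
#'   [MultiOmicsCohort-class]).
#' @return matrix / character vectors.
#' @export
setGeneric("values", function(object) standardGeneric("values"))
#' @rdname values
#' @export
setMethod("values", "OmicsMatrix", function(object) object@values)

#' @rdname values
#' @export
setGeneric("modalityName", function(object) standardGeneric("modalityName"))
#' @rdname values
#' @export
setMethod("modalityName", "OmicsMatrix", function(object) object@modality)

#' @rdname values
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))
#' @rdname values
#' @export
setMethod("sampleIDs", "OmicsMatrix", function(object) rownames(object@values))

#' @rdname values
#' @export
setGeneric("featureIDs", function(object) standardGeneric("featureIDs"))
#' @rdname values
#' @export
setMethod("featureIDs", "OmicsMatrix", function(object) colnames(object@values))

setMethod("show", "OmicsMatrix", function(object) {
  cat("OmicsMatrix <", object@modality, ">: ",
    nrow(object@values), " samples x ", ncol(object@values), " features; ",
    sum(is.na(object@values)), " missing\n",
    sep = ""
  )
})

#' MultiOmicsCohort: aligned multi-modality cohort with survival
#'
#' K omics matrices over the same ordered samples, plus survival follow-up
#' (months and event indicator) and a binary risk label per sample
#' (0 = short-term survivor, 1 = long-term survivor).
#'
#' @slot modalities list of [OmicsMatrix-class], identical ordered sample ids.
#' @slot survival data.frame with columns `sampleID`, `survivalMonths`,
#'   `eventObserved` (TRUE = death observed, FALSE = censored).
#' @slot labels integer vector of 0/1 per sample.
#' @slot cutoffYears positive numeric; the short/long dichotomization
#'   threshold in years.
#' @export
setClass("MultiOmicsCohort",
  representation(
    modalities = "list", survival = "data.frame",
    labels = "integer", cutoffYears = "numeric"
  ),
  validity = function(object) {
    msgs <- character()
    if (!length(object@modalities)) {
      return("at least one modality required")
    }
    if (!all(vapply(object@modalities, is, TRUE, "OmicsMatrix"))) {
      return("modalities must be OmicsMatrix objects")
    }
    ids <- sampleIDs(object@modalities[[1L]])
    for (om in object@modalities) {
      if (!identical(sampleIDs(om), ids)) {
        msgs <- c(msgs, "all modalities must share the same ordered sample ids")
        break
      }
    }
    sv <- object@survival
    need <- c("sampleID", "survivalMonths", "eventObserved")
    if (!all(need %in% names(sv))) {
      msgs <- c(msgs, paste(
        "survival must have columns",
        paste(need, collapse = ", ")
      ))
    } else {
      if (!identical(as.character(sv$sampleID), ids)) {
        msgs <- c(msgs, "survival table must cover the same samples in order")
      }
      if (any(sv$survivalMonths < 0, na.rm = TRUE)) {
        msgs <- c(msgs, "survivalMonths must be non-negative")
      }
    }
    if (length(object@labels) != length(ids) || !isBinary(object@labels)) {
      msgs <- c(msgs, "labels must be 0/1, one per sample")
    }
    if (length(object@cutoffYears) != 1L || object@cutoffYears <= 0) {
      msgs <- c(msgs, "cutoffYears must be a single positive number")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' Construct a MultiOmicsCohort
#'
#' @param modalities named list of [OmicsMatrix-class] objects sharing the
#'   same ordered samples.
#' @param survival data.frame with columns `sampleID`, `survivalMonths`,
#'   `eventObserved`, in the same sample order.
#' @param cutoffYears dichotomization threshold in years.
#' @param labels optional 0/1 vector (0 = short-term).  When `NULL`, labels
#'   are derived from observed survival time with [deriveLabels()] under the
#'   default `observed_time` policy.
#' @return a [MultiOmicsCohort-class].
#' @export
MultiOmicsCohort <- function(modalities, survival, cutoffYears, labels = NULL) {
  if (is.null(names(modalities))) {
    names(modalities) <- vapply(modalities, modalityName, "")
  }
  survival$sampleID <- as.character(survival$sampleID)
  if (is.null(labels)) {
    labels <- deriveLabels(survival, cutoffYears)$labels
  }
  new("MultiOmicsCohort",
    modalities = modalities, survival = survival,
    labels = as.integer(labels), cutoffYears = as.numeric(cutoffYears)
  )
}

#' @rdname values
#' @export
setMethod("sampleIDs", "MultiOmicsCohort", function(object) {
  sampleIDs(object@modalities[[1L]])
})

#' Cohort accessors
#'
#' @param object a [MultiOmicsCohort-class].
#' @return `modalities()` the list of OmicsMatrix; `cohortLabels()` the 0/1
#'   vector; `survivalTable()` the survival data.frame; `cutoffYears()` the
#'   threshold; `nModalities()`/`nSamples()` counts.
#' @export
setGeneric("modalities", function(object) standardGeneric("modalities"))
#' @rdname modalities
#' @export
setMethod("modalities", "MultiOmicsCohort", function(object) object@modalities)

#' @rdname modalities
#' @export
setGeneric("cohortLabels", function(object) standardGeneric("cohortLabels"))
#' @rdname modalities
#' @export
setMethod("cohortLabels", "MultiOmicsCohort", function(object) object@labels)

#' @rdname modalities
#' @export
setGeneric("survivalTable", function(object) standardGeneric("survivalTable"))
#' @rdname modalities
#' @export
setMethod("survivalTable", "MultiOmicsCohort", function(object) object@survival)

#' @rdname modalities
#' @export
setGeneric("cutoffYears", function(object) standardGeneric("cutoffYears"))
#' @rdname modalities
#' @export
setMethod("cutoffYears", "MultiOmicsCohort", function(object) object@cutoffYears)

#' @rdname modalities
#' @export
setGeneric("nModalities", function(object) standardGeneric("nModalities"))
#' @rdname modalities
#' @export
setMethod("nModalities", "MultiOmicsCohort", function(object) {
  length(object@modalities)
})

#' @rdname modalities
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname modalities
#' @export
setMethod("nSamples", "MultiOmicsCohort", function(object) {
  nrow(values(object@modalities[[1L]]))
})

setMethod("show", "MultiOmicsCohort", function(object) {
  dims <- vapply(object@modalities, function(m) ncol(values(m)), 0L)
  cat("MultiOmicsCohort: ", nSamples(object), " samples, ",
    nModalities(object), " modalities (",
    paste0(names(object@modalities), ":", dims, collapse = ", "),
    ")\n",
    sep = ""
  )
  tab <- table(factor(object@labels, levels = c(0, 1)))
  cat(
    "  labels: ", tab[["0"]], " short / ", tab[["1"]], " long (cut-off ",
    object@cutoffYears, " years); censored: ",
    sum(!object@survival$eventObserved), "/", nSamples(object), "\n",
    sep = ""
  )
})

#' FoldPlan: the stratified ten-fold rotation
#'
#' Each class is partitioned into `nFolds` near-equal subsets; round r uses
#' subset r for validation, the next seven subsets (cyclically) for
#' training and the remaining two for testing, with identical subset
#' indexing across classes.
#'
#' @slot nFolds integer (10).
#' @slot subsets list with one element per class; each is a list of
#'   `nFolds` integer vectors of sample indices (into the cohort).
#' @slot rounds list of `nFolds` lists with elements `validation`, `train`,
#'   `test`: integer sample indices pooled over classes.
#' @slot seed integer seed that produced the partition.
#' @export
setClass("FoldPlan",
  representation(
    nFolds = "integer", subsets = "list",
    rounds = "list", seed = "integer"
  ),
  validity = function(object) {
    msgs <- character()
    for (cls in names(object@subsets)) {
      parts <- object@subsets[[cls]]
      if (length(parts) != object@nFolds) {
        msgs <- c(msgs, "each class needs nFolds subsets")
      }
      all_idx <- sort(unlist(parts))
      if (anyDuplicated(all_idx)) {
        msgs <- c(msgs, "subsets within a class must be disjoint")
      }
    }
    if (length(object@rounds) != object@nFolds) {
      msgs <- c(msgs, "one round per fold required")
    }
    for (rd in object@rounds) {
      if (length(intersect(rd$validation, rd$train)) ||
        length(intersect(rd$validation, rd$test)) ||
        length(intersect(rd$train, rd$test))) {
        msgs <- c(msgs, "validation/train/test must be disjoint in each round")
        break
      }
    }
    if (length(msgs)) msgs else TRUE
  }
)

setMethod("show", "FoldPlan", function(object) {
  ns <- vapply(object@subsets, function(p) length(unlist(p)), 0L)
  cat("FoldPlan: ", object@nFolds, " folds, classes {",
    paste0(names(object@subsets), ": n=", ns, collapse = ", "),
    "}, seed ", object@seed, "\n",
    sep = ""
  )
  cat("  rotation per round: 1 validation / 7 train / 2 test subsets\n")
})

#' Round accessor for a FoldPlan
#'
#' @param plan a [FoldPlan-class].
#' @param round round number in `1..nFolds`.
#' @return list with integer index vectors `validation`, `train`, `test`.
#' @export
foldRound <- function(plan, round) {
  assertThat(round >= 1 && round <= plan@nFolds, "round out of range")
  plan@rounds[[round]]
}
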