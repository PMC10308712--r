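#' Read a delimited omics matrix
#'
#' Reads a TSV/CSV matrix with a header row of identifiers and a first
#' column of identifiers.  By default rows are samples and columns are
#' features; files distributed features-as-rows (both conventions occur in
#' public multi-omics releases) are handled with
#' `orientation = "features"`, which transposes after reading.  Cells that
#' are empty, `"NA"` or `"NaN"` become missing values.
#'
#' @param path file path.
#' @param modality label for the data type (e.g. `"mRNA"`).
#' @param orientation `"samples"` (rows are samples, default) or
#'   `"features"` (rows are features; transposed on read).
#' @param sep field separator; guessed from the extension when `NULL`
#'   (`.csv` gives `","`, anything else tab).
#' @return an [OmicsMatrix-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(rnorm(6), 3, 2,
#'   dimnames = list(paste0("s", 1:3), c("g1", "g2")))
#' writeOmicsMatrix(OmicsMatrix(m, "mRNA"), f)
#' om <- readOmicsMatrix(f, "mRNA")
#' @export
readOmicsMatrix <- function(path, modality = "omics",
                            orientation = c("samples", "features"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.table(path,
    header = TRUE, sep = sep, row.names = 1L,
    check.names = FALSE, na.strings = c("NA", "NaN", ""),
    colClasses = NA, stringsAsFactors = FALSE, comment.char = ""
  )
  bad <- !vapply(df, is.numeric, TRUE)
  if (any(bad)) {
    stop(
      "non-numeric values in column(s): ",
      paste(names(df)[bad], collapse = ", ")
    )
  }
  m <- as.matrix(df)
  if (orientation == "features") m <- t(m)
  if (anyDuplicated(rownames(m))) stop("duplicated sample ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicated feature ids in ", path)
  OmicsMatrix(m, modality)
}

#' Write an OmicsMatrix to a delimited file
#'
#' Inverse of [readOmicsMatrix()] (samples-as-rows orientation); missing
#' entries are written as `NA`.
#'
#' @param object an [OmicsMatrix-class].
#' @param path output path; `.csv` extension selects comma separation.
#' @return `path`, invisibly.
#' @export
writeOmicsMatrix <- function(object, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  m <- values(object)
  df <- data.frame(sampleID = rownames(m), m, check.names = FALSE)
  write.table(df, path,
    sep = sep, quote = FALSE, row.names = FALSE,
    col.names = TRUE, na = "NA"
  )
  invisible(path)
}

#' Read / write a survival table
#'
#' The survival table holds one row per sample with columns `sampleID`,
#' `survivalMonths` (non-negative) and `eventObserved` (TRUE/1 = death
#' observed, FALSE/0 = right-censored).  Legacy column names
#' (`sample_id`, `survival_months`, `event`) are accepted on read.
#'
#' @param path file path (TSV, or CSV by extension).
#' @return `readSurvivalTable`: a data.frame with the canonical columns.
#' @export
readSurvivalTable <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.table(path,
    header = TRUE, sep = sep, check.names = FALSE,
    stringsAsFactors = FALSE
  )
  ren <- c(
    sample_id = "sampleID", survival_months = "survivalMonths",
    event = "eventObserved"
  )
  for (old in names(ren)) {
    if (old %in% names(df) && !(ren[[old]] %in% names(df))) {
      names(df)[names(df) == old] <- ren[[old]]
    }
  }
  need <- c("sampleID", "survivalMonths", "eventObserved")
  assertThat(
    all(need %in% names(df)),
    paste("survival table needs columns", paste(need, collapse = ", "))
  )
  df$sampleID <- as.character(df$sampleID)
  df$survivalMonths <- as.numeric(df$survivalMonths)
  df$eventObserved <- as.logical(df$eventObserved)
  assertThat(all(df$survivalMonths >= 0), "survivalMonths must be >= 0")
  df[need]
}

#' @rdname readSurvivalTable
#' @param survival data.frame as returned by [readSurvivalTable()].
#' @export
writeSurvivalTable <- function(survival, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  write.table(survival, path,
    sep = sep, quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Dichotomize survival into short/long labels
#'
#' Samples surviving strictly less than `cutoffYears * 12` months are
#' short-term survivors (label 0); all others are long-term (label 1).
#' Under the default `observed_time` policy every sample is labeled from
#' its observed follow-up time regardless of censoring.  Under
#' `drop_early_censored`, samples censored before the cut-off — whose true
#' class is unknowable — are masked out.
#'
#' @param survival survival data.frame (see [readSurvivalTable()]).
#' @param cutoffYears positive threshold in years.
#' @param policy `"observed_time"` (default) or `"drop_early_censored"`.
#' @return list with `labels` (integer 0/1, `NA` where masked) and `keep`
#'   (logical mask of retained samples).
#' @examples
#' sv <- data.frame(
#'   sampleID = c("a", "b"), survivalMonths = c(14, 48),
#'   eventObserved = c(TRUE, TRUE)
#' )
#' deriveLabels(sv, 2)$labels # 0 1
#' @export
deriveLabels <- function(survival, cutoffYears,
                         policy = c("observed_time", "drop_early_censored")) {
  policy <- match.arg(policy)
  assertThat(cutoffYears > 0, "cutoffYears must be positive")
  cutoffMonths <- cutoffYears * 12
  labels <- ifelse(survival$survivalMonths < cutoffMonths, 0L, 1L)
  keep <- rep(TRUE, nrow(survival))
  if (policy == "drop_early_censored") {
    keep <- !(!survival$eventObserved & survival$survivalMonths < cutoffMonths)
    labels[!keep] <- NA_integer_
  }
  list(labels = as.integer(labels), keep = keep)
}

#' Restrict a cohort to a subset of samples
#'
#' @param cohort a [MultiOmicsCohort-class].
#' @param idx integer or logical sample index.
#' @return a [MultiOmicsCohort-class] over the selected samples.
#' @export
subsetCohort <- function(cohort, idx) {
  mods <- lapply(modalities(cohort), function(om) {
    OmicsMatrix(values(om)[idx, , drop = FALSE], modalityName(om))
  })
  MultiOmicsCohort(mods, survivalTable(cohort)[idx, , drop = FALSE],
    cutoffYears(cohort),
    labels = cohortLabels(cohort)[idx]
  )
}

#' Single-modality and concatenation views of a cohort
#'
#' `singleModalityCohort()` keeps one modality; `concatCohort()` replaces
#' the K modalities by their column-wise concatenation (the trivial
#' early-fusion baseline).  Both keep survival and labels untouched.
#'
#' @param cohort a [MultiOmicsCohort-class].
#' @param k modality index or name.
#' @return a [MultiOmicsCohort-class].
#' @export
singleModalityCohort <- function(cohort, k) {
  MultiOmicsCohort(modalities(cohort)[k], survivalTable(cohort),
    cutoffYears(cohort),
    labels = cohortLabels(cohort)
  )
}

#' @rdname singleModalityCohort
#' @export
concatCohort <- function(cohort) {
  mats <- lapply(modalities(cohort), function(om) {
    m <- values(om)
    colnames(m) <- paste(modalityName(om), colnames(m), sep = ".")
    m
  })
  MultiOmicsCohort(
    list(concat = OmicsMatrix(do.call(cbind, mats), "concat")),
    survivalTable(cohort), cutoffYears(cohort),
    labels = cohortLabels(cohort)
  )
}

#' Write a cohort to a directory of delimited files
#'
#' One `<modality>.tsv` per modality plus `survival.tsv` and `labels.tsv`.
#'
#' @param cohort a [MultiOmicsCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (om in modalities(cohort)) {
    writeOmicsMatrix(om, file.path(dir, paste0(modalityName(om), ".tsv")))
  }
  writeSurvivalTable(survivalTable(cohort), file.path(dir, "survival.tsv"))
  write.table(
    data.frame(
      sampleID = sampleIDs(cohort),
      label = cohortLabels(cohort)
    ),
    file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' Read a cohort directory written by [writeCohort()]
#'
#' @param dir directory containing `<modality>.tsv` files, `survival.tsv`
#'   and optionally `labels.tsv`.
#' @param cutoffYears dichotomization threshold (used when no labels file).
#' @return a [MultiOmicsCohort-class].
#' @export
readCohort <- function(dir, cutoffYears = 2) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  special <- basename(files) %in% c("survival.tsv", "labels.tsv")
  modFiles <- files[!special]
  assertThat(length(modFiles) > 0, "no modality files found")
  mods <- lapply(modFiles, function(f) {
    readOmicsMatrix(f, sub("\\.tsv$", "", basename(f)))
  })
  survival <- readSurvivalTable(file.path(dir, "survival.tsv"))
  labels <- NULL
  lf <- file.path(dir, "labels.tsv")
  if (file.exists(lf)) {
    lt <- read.table(lf, header = TRUE, sep = "\t")
    labels <- as.integer(lt$label)
  }
  MultiOmicsCohort(mods, survival, cutoffYears, labels = labels)
}
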