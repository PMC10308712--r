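#' Preprocess an omics matrix
#'
#' Applies, in this fixed order: (i) remove samples with more than
#' `missingSampleFrac` missing entries; (ii) remove features with more than
#' `missingFeatureFrac` missing values; (iii) impute the remaining missing
#' entries from the `knnK` nearest samples (Euclidean distance over
#' co-observed features); (iv) z-score every surviving feature to mean 0,
#' sd 1 across samples.  The order matters: filtering before imputation
#' keeps heavily missing rows/columns from polluting the neighbourhoods.
#'
#' @param object an [OmicsMatrix-class], possibly with `NA` entries.
#' @param missingSampleFrac drop samples with a larger missing fraction
#'   (default 0.2).
#' @param missingFeatureFrac drop features with a larger missing fraction
#'   (default 0.2).
#' @param knnK number of nearest neighbours for imputation (default 5).
#' @param zscore set `FALSE` to skip step (iv).
#' @return a preprocessed [OmicsMatrix-class].  Zero-variance features are
#'   set to all-zeros with a warning rather than dividing by zero.
#' @export
preprocessOmicsMatrix <- function(object, missingSampleFrac = 0.2,
                                  missingFeatureFrac = 0.2, knnK = 5,
                                  zscore = TRUE) {
  assertThat(knnK >= 1, "knnK must be >= 1")
  m <- values(object)
  ## (i) sample filter
  sampleMiss <- rowMeans(is.na(m))
  m <- m[sampleMiss <= missingSampleFrac, , drop = FALSE]
  ## (ii) feature filter
  featMiss <- colMeans(is.na(m))
  m <- m[, featMiss <= missingFeatureFrac, drop = FALSE]
  ## (iii) kNN imputation
  if (anyNA(m)) m <- knnImpute(m, knnK)
  ## (iv) z-score
  if (zscore) m <- zscoreColumns(m)
  OmicsMatrix(m, modalityName(object))
}

#' k-nearest-neighbour imputation
#'
#' For each missing entry `(i, j)`, ranks the other samples that observe
#' feature `j` by Euclidean distance to sample `i` computed over the
#' features observed in both samples (root mean squared difference, so
#' differing overlap sizes stay comparable), and imputes the mean of
#' feature `j` over the `k` nearest.  Falls back to the feature mean when
#' no neighbour with an overlap exists.
#'
#' @param m numeric matrix, samples x features, with `NA`s.
#' @param k number of neighbours.
#' @return the matrix with all `NA`s filled.
#' @export
knnImpute <- function(m, k = 5) {
  n <- nrow(m)
  obs <- !is.na(m)
  missRows <- which(rowSums(!obs) > 0)
  for (i in missRows) {
    ## RMS distance over co-observed features, to every other sample
    d <- rep(NA_real_, n)
    xi <- m[i, ]
    oi <- obs[i, ]
    for (j in seq_len(n)) {
      if (j == i) next
      ov <- oi & obs[j, ]
      if (!any(ov)) next
      d[j] <- sqrt(mean((xi[ov] - m[j, ov])^2))
    }
    for (f in which(!oi)) {
      cand <- which(obs[, f] & !is.na(d))
      if (!length(cand)) {
        m[i, f] <- mean(m[, f], na.rm = TRUE)
        next
      }
      nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      m[i, f] <- mean(m[nb, f])
    }
  }
  m
}

#' Column z-scoring with a zero-variance guard
#'
#' @param m numeric matrix without missing values.
#' @return matrix with each column standardized to mean 0, sd 1; constant
#'   columns become all-zeros with a warning.
#' @export
zscoreColumns <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2L, sd)
  zero <- s < .Machine$double.eps^0.5
  if (any(zero)) {
    warning(
      sum(zero), " zero-variance feature(s) set to all-zeros: ",
      paste(head(colnames(m)[zero], 5), collapse = ", ")
    )
    s[zero] <- 1
  }
  out <- sweep(sweep(m, 2L, mu, "-"), 2L, s, "/")
  out[, zero] <- 0
  out
}
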