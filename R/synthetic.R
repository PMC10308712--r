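#' Specification for a synthetic multi-omics cohort
#'
#' The generator plants a low-dimensional latent structure: one shared
#' factor block `zShared` entering every modality and one specific factor
#' block `zSpecific[[k]]` per modality.  Class signal enters as a mean
#' shift on the latents (`sharedEffect` on the shared block,
#' `specificEffects[k]` on modality k's specific block, applied to the
#' long-term class).  Observed features are a random orthonormal loading of
#' the latents plus Gaussian noise, z-scored per feature.  Survival times
#' are exponential with a higher hazard for the short-term class;
#' independent exponential censoring is calibrated so the expected
#' censored fraction equals `censorRate`.
#'
#' @param nSamples number of patients.
#' @param classProportions length-2 vector `(short, long)` summing to 1.
#' @param modalityDims K positive feature dimensions.
#' @param dShared,dSpecific latent dimensions of the shared / per-modality
#'   specific blocks.
#' @param sharedEffect class-mean shift on the shared latents.
#' @param specificEffects K class-mean shifts, one per modality.
#' @param noiseSd feature noise standard deviation (>= 0).
#' @param baselineHazard long-class event hazard per month (default 1/60,
#'   i.e. mean survival 60 months).
#' @param hazardRatio short-class hazard multiplier (default 5).
#' @param censorRate expected censored fraction in `[0, 1)`.
#' @param cutoffYears dichotomization threshold stored on the cohort.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `syntheticSpec` list.
#' @export
syntheticSpec <- function(nSamples = 300L,
                          classProportions = c(0.5, 0.5),
                          modalityDims = c(600L, 150L, 400L),
                          dShared = 5L, dSpecific = 5L,
                          sharedEffect = 0.8,
                          specificEffects = rep(0.5, length(modalityDims)),
                          noiseSd = 0.5,
                          baselineHazard = 1 / 60, hazardRatio = 5,
                          censorRate = 0.2, cutoffYears = 2,
                          seed = 1L) {
  spec <- list(
    nSamples = as.integer(nSamples),
    classProportions = as.numeric(classProportions),
    modalityDims = as.integer(modalityDims),
    dShared = as.integer(dShared), dSpecific = as.integer(dSpecific),
    sharedEffect = sharedEffect,
    specificEffects = as.numeric(specificEffects),
    noiseSd = noiseSd,
    baselineHazard = baselineHazard, hazardRatio = hazardRatio,
    censorRate = censorRate, cutoffYears = cutoffYears,
    seed = as.integer(seed)
  )
  assertThat(
    length(spec$classProportions) == 2L &&
      all(spec$classProportions > 0) && all(spec$classProportions < 1) &&
      abs(sum(spec$classProportions) - 1) < 1e-8,
    "classProportions must be two values in (0,1) summing to 1"
  )
  assertThat(all(spec$modalityDims >= 1L), "modalityDims must be positive")
  assertThat(
    length(spec$specificEffects) == length(spec$modalityDims),
    "one specificEffect per modality required"
  )
  assertThat(spec$noiseSd >= 0, "noiseSd must be >= 0")
  assertThat(
    spec$censorRate >= 0 && spec$censorRate < 1,
    "censorRate must be in [0, 1)"
  )
  assertThat(
    spec$baselineHazard > 0 && spec$hazardRatio > 0,
    "hazards must be positive"
  )
  class(spec) <- "syntheticSpec"
  spec
}

#' @export
print.syntheticSpec <- function(x, ...) {
  cat("syntheticSpec: n=", x$nSamples, ", K=", length(x$modalityDims),
    " dims (", paste(x$modalityDims, collapse = "/"),
    "), latents ", x$dShared, "+", x$dSpecific,
    ", effects shared=", x$sharedEffect, " specific=(",
    paste(x$specificEffects, collapse = ","), "), noise ", x$noiseSd,
    ", censor ", x$censorRate, ", seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

## censoring hazard c solving sum_g p_g * c/(c + lambda_g) = target
solveCensorHazard <- function(target, props, hazards) {
  if (target <= 0) {
    return(0)
  }
  f <- function(cc) sum(props * cc / (cc + hazards)) - target
  uniroot(f, c(1e-10, 1e6), tol = 1e-12)$root
}

#' Generate a synthetic multi-omics cohort
#'
#' Draws labels by class proportion (deterministic counts, shuffled order),
#' latents with class-mean shifts, per-modality loadings with orthonormal
#' columns (so the planted shared and specific subspaces are identifiable),
#' Gaussian feature noise, exponential survival with a class hazard ratio
#' and calibrated exponential censoring.  Bit-identical given the seed.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `cohort` (a [MultiOmicsCohort-class]) and `truth`
#'   (list: `zShared` N x dShared, `zSpecific` list of N x dSpecific,
#'   `loadings` list of q_k x (dShared+dSpecific), `labels`,
#'   `trueMonths`, `censorMonths`).
#' @examples
#' gen <- generateCohort(syntheticSpec(
#'   nSamples = 60, modalityDims = c(40, 15, 30), seed = 7
#' ))
#' gen$cohort
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  K <- length(spec$modalityDims)
  n <- spec$nSamples
  withSeed(spec$seed, {
    nShort <- round(n * spec$classProportions[1L])
    labels <- sample(rep(c(0L, 1L), c(nShort, n - nShort)))
    zShared <- matrix(rnorm(n * spec$dShared), n, spec$dShared) +
      spec$sharedEffect * labels
    zSpecific <- lapply(seq_len(K), function(k) {
      matrix(rnorm(n * spec$dSpecific), n, spec$dSpecific) +
        spec$specificEffects[k] * labels
    })
    d <- spec$dShared + spec$dSpecific
    loadings <- lapply(seq_len(K), function(k) {
      q <- spec$modalityDims[k]
      assertThat(q >= d, "modality dim must be >= dShared + dSpecific")
      qr.Q(qr(matrix(rnorm(q * d), q, d)))
    })
    sampleNames <- sprintf("S%04d", seq_len(n))
    modNames <- if (K == 3L) {
      c("mRNA", "miRNA", "DNAmeth")
    } else {
      paste0("mod", seq_len(K))
    }
    mods <- lapply(seq_len(K), function(k) {
      Z <- cbind(zShared, zSpecific[[k]])
      X <- Z %*% t(loadings[[k]])
      if (spec$noiseSd > 0) {
        X <- X + spec$noiseSd * matrix(rnorm(length(X)), nrow(X))
      }
      dimnames(X) <- list(
        sampleNames,
        paste0(modNames[k], "_f", seq_len(ncol(X)))
      )
      OmicsMatrix(zscoreColumns(X), modNames[k])
    })
    names(mods) <- modNames
    ## survival: exponential event times, class hazard ratio on the short class
    hazards <- ifelse(labels == 0L,
      spec$baselineHazard * spec$hazardRatio, spec$baselineHazard
    )
    trueMonths <- rexp(n, rate = hazards)
    cHaz <- solveCensorHazard(
      spec$censorRate, spec$classProportions,
      spec$baselineHazard * c(spec$hazardRatio, 1)
    )
    censorMonths <- if (cHaz > 0) rexp(n, rate = cHaz) else rep(Inf, n)
    observed <- pmin(trueMonths, censorMonths)
    event <- trueMonths <= censorMonths
    survival <- data.frame(
      sampleID = sampleNames,
      survivalMonths = observed,
      eventObserved = event
    )
    cohort <- MultiOmicsCohort(mods, survival, spec$cutoffYears,
      labels = labels
    )
    truth <- list(
      zShared = zShared, zSpecific = zSpecific, loadings = loadings,
      labels = labels, trueMonths = trueMonths, censorMonths = censorMonths,
      spec = spec
    )
    list(cohort = cohort, truth = truth)
  })
}

#' Named benchmark presets for the synthetic generator
#'
#' Three study conditions exercising different placements of the class
#' signal:
#' \describe{
#'   \item{`shared-only`}{all class signal in the shared latent block
#'     (specific effects 0); any single modality suffices.}
#'   \item{`complementary`}{no shared signal; each modality's specific
#'     block carries an equal share, so no single modality sees the full
#'     class signal but the integrated representation does.}
#'   \item{`mixed`}{both shared and specific signal, with the very
#'     different modality dimensionalities (2000/400/1500) and mild class
#'     imbalance typical of dichotomized TCGA cohorts.}
#' }
#'
#' @param seed integer; presets use `seed`, `seed + 1`, `seed + 2`.
#' @return named list of [syntheticSpec()] objects.
#' @export
benchmarkSuite <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    "shared-only" = syntheticSpec(
      nSamples = 200L, classProportions = c(0.5, 0.5),
      modalityDims = c(300L, 100L, 200L),
      sharedEffect = 1.0, specificEffects = c(0, 0, 0),
      noiseSd = 0.3, seed = seed
    ),
    "complementary" = syntheticSpec(
      nSamples = 300L, classProportions = c(0.5, 0.5),
      modalityDims = c(300L, 80L, 200L),
      sharedEffect = 0, specificEffects = c(0.6, 0.6, 0.6),
      noiseSd = 0.5, seed = seed + 1L
    ),
    "mixed" = syntheticSpec(
      nSamples = 300L, classProportions = c(0.6, 0.4),
      modalityDims = c(2000L, 400L, 1500L),
      sharedEffect = 0.8, specificEffects = c(0.5, 0.5, 0.5),
      noiseSd = 0.5, seed = seed + 2L
    )
  )
}

#' Serialize ground truth to plain-text files
#'
#' Writes the planted latents and loadings as TSV plus a JSON manifest of
#' the generating spec, alongside [writeCohort()] output.
#'
#' @param truth the `truth` element of [generateCohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeGroundTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(m, f) {
    write.table(m, file.path(dir, f),
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  }
  wt(truth$zShared, "z_shared.tsv")
  for (k in seq_along(truth$zSpecific)) {
    wt(truth$zSpecific[[k]], sprintf("z_specific_%d.tsv", k))
    wt(truth$loadings[[k]], sprintf("loading_%d.tsv", k))
  }
  spec <- truth$spec
  class(spec) <- NULL
  jsonlite::write_json(
    c(spec, list(labels = truth$labels)),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
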