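# Fixtures and independent oracles used across the suite.  Oracles are
# deliberately naive re-derivations (loops, exhaustive enumeration) kept
# separate from the package's code paths.

tinyOmics <- function(n = 5, q = 4, seed = 1, modality = "mRNA") {
  set.seed(seed)
  m <- matrix(rnorm(n * q), n, q,
    dimnames = list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:q))
  )
  OmicsMatrix(m, modality)
}

tinyCohort <- function(n = 60, dims = c(30, 10, 20), seed = 7, ...) {
  generateCohort(syntheticSpec(
    nSamples = n, modalityDims = dims,
    seed = seed, ...
  ))
}

tinyNet <- function() {
  netConfig(hiddenSizes = c(10, 6), embedSize = 4, classifierHidden = 4)
}

# concordance-probability AUC: exhaustive positive/negative pair counting,
# ties credited one half
aucByPairs <- function(yTrue, scores, positive = 0) {
  pos <- scores[yTrue == positive]
  neg <- scores[yTrue != positive]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# two-group log-rank statistic from first principles: walk the risk table
# over distinct event times, accumulate observed vs expected events and
# the hypergeometric variance for group 1
logrankByRiskTable <- function(times, events, groups) {
  groups <- as.integer(as.factor(groups))
  eventTimes <- sort(unique(times[events]))
  O1 <- 0
  E1 <- 0
  V <- 0
  for (t in eventTimes) {
    atRisk <- times >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & groups == 1L)
    d <- sum(events & times == t)
    d1 <- sum(events & times == t & groups == 1L)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) {
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  (O1 - E1)^2 / V
}

# brute-force kNN imputation oracle: full distance ranking per missing cell
knnImputeOracle <- function(m, k) {
  out <- m
  for (i in seq_len(nrow(m))) {
    miss <- which(is.na(m[i, ]))
    if (!length(miss)) next
    d <- rep(NA_real_, nrow(m))
    for (j in seq_len(nrow(m))) {
      if (j == i) next
      ov <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (any(ov)) d[j] <- sqrt(mean((m[i, ov] - m[j, ov])^2))
    }
    for (f in miss) {
      cand <- which(!is.na(m[, f]) & !is.na(d))
      if (!length(cand)) {
        out[i, f] <- mean(m[, f], na.rm = TRUE)
      } else {
        nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
        out[i, f] <- mean(m[nb, f])
      }
    }
  }
  out
}

# central finite difference of f at x, elementwise
numericGradient <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x
    xp[i] <- x[i] + eps
    xm <- x
    xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

relErr <- function(a, b) {
  max(abs(a - b) / pmax(1e-8, abs(a) + abs(b)))
}
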