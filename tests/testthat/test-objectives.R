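test_that("orthogonality loss matches hand-computed values", {
  # disjoint row support -> orthogonal feature columns -> zero loss
  Hc <- rbind(c(1, 2), c(3, 4), c(0, 0), c(0, 0))
  Hs <- rbind(c(0, 0), c(0, 0), c(5, 6), c(7, 8))
  expect_equal(orthogonalityLoss(Hc, Hs, normalize = FALSE), 0)

  # identity pair: ||I||_F^2 = 2, batch-normalized 2 / 2^2 = 0.5
  expect_equal(orthogonalityLoss(diag(2), diag(2), normalize = FALSE), 2)
  expect_equal(orthogonalityLoss(diag(2), diag(2)), 0.5)

  # homogeneity: scaling one argument by c scales the loss by c^2
  set.seed(1)
  A <- matrix(rnorm(12), 4)
  B <- matrix(rnorm(12), 4)
  for (c in c(0.5, 2, 3)) {
    expect_equal(
      orthogonalityLoss(A, c * B),
      c^2 * orthogonalityLoss(A, B)
    )
  }
  expect_error(orthogonalityLoss(A, B[, 1:2]), "shape")
})

test_that("distance loss averages pairwise squared distances over modality pairs", {
  # K = 2, N = 1: (1/2) * ||(0,0) - (3,4)||^2 = 12.5
  expect_equal(
    distanceLoss(list(matrix(0, 1, 2), matrix(c(3, 4), 1))),
    12.5
  )
  # identical shared outputs -> 0
  m <- matrix(rnorm(12), 4)
  expect_equal(distanceLoss(list(m, m, m)), 0)

  # K = 3: mean over the three unordered pairs, against a brute-force loop
  set.seed(2)
  hs <- lapply(1:3, function(k) matrix(rnorm(20), 5))
  pairLoss <- function(a, b) sum((a - b)^2) / (2 * nrow(a))
  manual <- mean(c(
    pairLoss(hs[[1]], hs[[2]]),
    pairLoss(hs[[1]], hs[[3]]),
    pairLoss(hs[[2]], hs[[3]])
  ))
  expect_equal(distanceLoss(hs), manual)

  expect_warning(z <- distanceLoss(list(m)), ">= 2 modalities")
  expect_equal(z, 0)
})

test_that("pairwise distance is a Euclidean norm", {
  expect_equal(pairwiseDistance(c(0, 0), c(3, 4)), 5)
  expect_equal(pairwiseDistance(c(1, 1), c(1, 1)), 0)
  a <- rnorm(6)
  b <- rnorm(6)
  expect_equal(pairwiseDistance(a, b), pairwiseDistance(b, a))
})

test_that("contrastive loss matches the margin hinge form", {
  # same-class coincident pair: no pull needed
  expect_equal(contrastiveLoss(0, 1, margin = 2), 0)
  # different-class pair at or beyond the margin: hinge inactive
  expect_equal(contrastiveLoss(2, 0, margin = 2), 0)
  expect_equal(contrastiveLoss(5, 0, margin = 2), 0)
  # two pairs with margin 2: (1/4) * (1^2 + (2-1)^2) = 0.5
  expect_equal(contrastiveLoss(c(1, 1), c(1, 0), margin = 2), 0.5)
  # empty pair list
  expect_equal(contrastiveLoss(numeric(0), numeric(0), margin = 2), 0)

  # continuity at the hinge boundary
  eps <- 1e-8
  below <- contrastiveLoss(2 - eps, 0, margin = 2)
  above <- contrastiveLoss(2 + eps, 0, margin = 2)
  expect_lt(abs(below - above), 1e-16 + 1e-12)
})

test_that("total loss is the weighted component sum, linear in each weight", {
  w <- lossWeights(wCE = 1, wDiff = 0.2, wDiss = 0.3, wCon = 0.4)
  r <- totalLoss(1.5, 2, 3, 4, w)
  expect_equal(r$total, 1.5 + 0.2 * 2 + 0.3 * 3 + 0.4 * 4)

  wCEonly <- lossWeights(wCE = 1, wDiff = 0, wDiss = 0, wCon = 0)
  expect_equal(totalLoss(1.5, 2, 3, 4, wCEonly)$total, 1.5)

  w2 <- lossWeights(wCE = 1, wDiff = 0.2, wDiss = 0.3, wCon = 0.8)
  expect_equal(
    totalLoss(1.5, 2, 3, 4, w2)$total - r$total,
    0.4 * 4
  )
})

test_that("every loss is non-negative on random inputs", {
  set.seed(7)
  for (i in 1:20) {
    A <- matrix(rnorm(24), 6)
    B <- matrix(rnorm(24), 6)
    expect_gte(orthogonalityLoss(A, B), 0)
    expect_gte(distanceLoss(list(A, B)), 0)
    d <- runif(5, 0, 4)
    y <- rbinom(5, 1, 0.5)
    expect_gte(contrastiveLoss(d, y, margin = 2), 0)
  }
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(11)
  Hc <- matrix(rnorm(32), 8, 4)
  Hs <- matrix(rnorm(32), 8, 4)

  g <- orthogonalityLoss(Hc, Hs, grad = TRUE)
  numC <- numericGradient(function(x) {
    orthogonalityLoss(matrix(x, 8), Hs)
  }, as.numeric(Hc))
  numS <- numericGradient(function(x) {
    orthogonalityLoss(Hc, matrix(x, 8))
  }, as.numeric(Hs))
  expect_lt(relErr(as.numeric(g$gHc), numC), 1e-6)
  expect_lt(relErr(as.numeric(g$gHs), numS), 1e-6)

  hs <- lapply(1:3, function(k) matrix(rnorm(32), 8, 4))
  gd <- distanceLoss(hs, grad = TRUE)
  for (k in 1:3) {
    num <- numericGradient(function(x) {
      h2 <- hs
      h2[[k]] <- matrix(x, 8)
      distanceLoss(h2)
    }, as.numeric(hs[[k]]))
    expect_lt(relErr(as.numeric(gd$gList[[k]]), num), 1e-6)
  }

  d <- runif(8, 0.1, 4)
  y <- rbinom(8, 1, 0.5)
  gc <- contrastiveLoss(d, y, margin = 2, grad = TRUE)
  num <- numericGradient(function(x) contrastiveLoss(x, y, margin = 2), d)
  expect_lt(relErr(gc$gd, num), 1e-6)

  logits <- matrix(rnorm(16), 8, 2)
  yy <- rbinom(8, 1, 0.5)
  ge <- crossEntropyLoss(logits, yy, grad = TRUE)
  num <- numericGradient(function(x) {
    crossEntropyLoss(matrix(x, 8), yy)
  }, as.numeric(logits))
  expect_lt(relErr(as.numeric(ge$gLogits), num), 1e-6)
})

test_that("backpropagated network gradients match finite differences", {
  gen <- tinyCohort(n = 9, dims = c(12, 10, 11), dShared = 3, dSpecific = 3)
  xs <- lapply(modalities(gen$cohort), function(o) unname(values(o)))
  y <- cohortLabels(gen$cohort)
  w <- lossWeights(wCE = 1, wDiff = 0.3, wDiss = 0.25, wCon = 0.2)
  net <- netConfig(hiddenSizes = c(6, 5), embedSize = 3, classifierHidden = 3)

  getAt <- function(tree, path) {
    for (p in path) tree <- tree[[p]]
    tree
  }
  setAt <- function(tree, path, val) {
    if (length(path) == 1L) {
      tree[[path[[1]]]] <- val
      return(tree)
    }
    tree[[path[[1]]]] <- setAt(tree[[path[[1]]]], path[-1], val)
    tree
  }
  checkPath <- function(model, res, path, nProbe = 4) {
    W <- getAt(model$params, path)
    G <- getAt(res$grads, path)
    set.seed(13)
    for (t in seq_len(nProbe)) {
      i <- sample(length(W), 1)
      eps <- 1e-5
      fAt <- function(delta) {
        W2 <- W
        W2[i] <- W[i] + delta
        m2 <- model
        m2$params <- setAt(model$params, path, W2)
        modelLoss(m2, xs, y, w)$report$total
      }
      num <- (fAt(eps) - fAt(-eps)) / (2 * eps)
      expect_lt(relErr(num, G[i]), 1e-4)
    }
  }

  model <- buildModel(mappingSpec(c(12, 10, 11)), net, seed = 6)
  res <- modelLoss(model, xs, y, w, grad = TRUE)
  for (path in list(
    list("mapping", 1, "W", 1), list("mapping", 2, "b", 2),
    list("shared", 1, "W", 3), list("shared", 3, "W", 1),
    list("specific", 2, "W", 2), list("classifier", "W", 1),
    list("classifier", "W", 2), list("classifier", "b", 1)
  )) {
    checkPath(model, res, path)
  }

  # ICLL mode and tied shared weights follow the same gradients rules
  wIcll <- w
  wIcll$constraintLayers <- "last"
  resIcll <- modelLoss(model, xs, y, wIcll, grad = TRUE)
  expect_false(identical(res$grads$shared, resIcll$grads$shared))

  tied <- buildModel(mappingSpec(c(12, 10, 11)), net,
    seed = 6,
    tieSharedWeights = TRUE
  )
  resTied <- modelLoss(tied, xs, y, w, grad = TRUE)
  checkPath(tied, resTied, list("shared", 1, "W", 2))
})

test_that("constraint layer selection changes which activations carry penalties", {
  gen <- tinyCohort(n = 8, dims = c(12, 10, 11), dShared = 3, dSpecific = 3)
  xs <- lapply(modalities(gen$cohort), function(o) unname(values(o)))
  y <- cohortLabels(gen$cohort)
  model <- buildModel(
    mappingSpec(c(12, 10, 11)),
    netConfig(hiddenSizes = c(6, 5), embedSize = 3, classifierHidden = 3),
    seed = 2
  )
  wAll <- lossWeights(wDiff = 1, wDiss = 1, wCon = 0)
  wLast <- lossWeights(wDiff = 1, wDiss = 1, wCon = 0, constraintLayers = "last")
  rAll <- modelLoss(model, xs, y, wAll)$report
  rLast <- modelLoss(model, xs, y, wLast)$report
  # the all-layer sum strictly contains the last-layer term
  expect_gt(rAll$lDiff, rLast$lDiff)
  expect_gt(rAll$lDiss, rLast$lDiss)
  # with the constraints unweighted the two configurations coincide
  w0 <- lossWeights(wDiff = 0, wDiss = 0, wCon = 0)
  w0Last <- lossWeights(wDiff = 0, wDiss = 0, wCon = 0, constraintLayers = "last")
  expect_equal(
    modelLoss(model, xs, y, w0)$report$total,
    modelLoss(model, xs, y, w0Last)$report$total
  )
})
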