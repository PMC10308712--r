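## Minimal dense-network machinery on BLAS matrix ops.
## A "stack" is a list(W = list of in x out matrices, b = list of length-out
## vectors or NULL, act = character per layer: "relu" or "identity").

makeStack <- function(sizes, act, bias = TRUE) {
  L <- length(sizes) - 1L
  act <- rep_len(act, L)
  W <- vector("list", L)
  b <- if (bias) vector("list", L) else NULL
  for (l in seq_len(L)) {
    fanIn <- sizes[l]
    ## He initialization, suited to rectifier layers
    W[[l]] <- matrix(
      rnorm(fanIn * sizes[l + 1L], sd = sqrt(2 / fanIn)),
      fanIn, sizes[l + 1L]
    )
    if (bias) b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b, act = act)
}

applyAct <- function(z, act) {
  if (act == "relu") {
    z[z < 0] <- 0
    z
  } else {
    z
  }
}

## Forward pass; returns list of post-activation matrices per layer.
stackForward <- function(stack, X) {
  acts <- vector("list", length(stack$W))
  a <- X
  for (l in seq_along(stack$W)) {
    z <- a %*% stack$W[[l]]
    if (!is.null(stack$b)) {
      z <- z + rep(stack$b[[l]], each = nrow(z))
    }
    a <- applyAct(z, stack$act[l])
    acts[[l]] <- a
  }
  acts
}

## Backward pass.  gradTop: gradient w.r.t. the final post-activation;
## extraGrads: optional list adding gradients at every layer's
## post-activation (the layer-by-layer constraint terms inject here).
## Returns list(gW, gb, gX).
stackBackward <- function(stack, X, acts, gradTop, extraGrads = NULL) {
  L <- length(stack$W)
  gW <- vector("list", L)
  gb <- if (!is.null(stack$b)) vector("list", L) else NULL
  ga <- gradTop
  for (l in rev(seq_len(L))) {
    if (!is.null(extraGrads) && !is.null(extraGrads[[l]])) {
      ga <- ga + extraGrads[[l]]
    }
    gz <- if (stack$act[l] == "relu") ga * (acts[[l]] > 0) else ga
    below <- if (l == 1L) X else acts[[l - 1L]]
    gW[[l]] <- crossprod(below, gz)
    if (!is.null(gb)) gb[[l]] <- colSums(gz)
    ga <- tcrossprod(gz, stack$W[[l]])
  }
  list(gW = gW, gb = gb, gX = ga)
}

treeAdd <- function(a, b) {
  if (is.null(a)) {
    return(b)
  }
  if (is.null(b)) {
    return(a)
  }
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- treeAdd(a[[i]], b[[i]])
    a
  } else {
    a + b
  }
}

## Flatten all numeric leaves of a parameter tree (depth-first, in list
## order) into one vector; `fillNumericLeaves` is the inverse given the
## original tree as the shape template.  Non-numeric leaves (activation
## labels) and NULLs are skipped consistently.
flattenNumericLeaves <- function(tree) {
  acc <- vector("list", 64L)
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      for (el in x) walk(el)
    } else if (is.numeric(x)) {
      n <<- n + 1L
      if (n > length(acc)) acc[[2L * n]] <<- NULL
      acc[[n]] <<- as.numeric(x)
    }
  }
  walk(tree)
  unlist(acc[seq_len(n)], use.names = FALSE)
}

fillNumericLeaves <- function(tree, vec) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) {
      for (i in seq_along(x)) {
        xi <- x[[i]]
        if (is.list(xi)) {
          x[[i]] <- fill(xi)
        } else if (is.numeric(xi)) {
          len <- length(xi)
          xi[] <- vec[(pos + 1L):(pos + len)]
          pos <<- pos + len
          x[[i]] <- xi
        }
      }
    }
    x
  }
  out <- fill(tree)
  stopifnot(pos == length(vec))
  out
}

## Fresh deep copy of a parameter tree (numeric leaves reallocated), so
## in-place optimizer updates cannot touch the caller's model.
duplicateTree <- function(tree) {
  if (is.list(tree)) {
    lapply(tree, duplicateTree)
  } else if (is.numeric(tree)) {
    tree + 0
  } else {
    tree
  }
}

## References to the numeric leaves of a tree, in canonical (depth-first)
## order.  The returned list shares storage with the tree: in-place C++
## updates through these references update the tree itself.
collectLeafRefs <- function(tree) {
  acc <- list()
  walk <- function(x) {
    if (is.list(x)) {
      for (el in x) walk(el)
    } else if (is.numeric(x)) {
      acc[[length(acc) + 1L]] <<- x
    }
  }
  walk(tree)
  acc
}

## Gradient leaves in the same canonical order as collectLeafRefs on the
## parameter tree, matching list elements by name (the gradient tree lacks
## the activation labels).  No copying: just pointers.
collectGradLeaves <- function(params, grads) {
  acc <- list()
  walk <- function(p, g) {
    if (is.list(p)) {
      keys <- names(p)
      for (i in seq_along(p)) {
        gi <- if (!is.null(keys) && nzchar(keys[i]) && !is.null(g)) {
          g[[keys[i]]]
        } else if (!is.null(g) && i <= length(g)) {
          g[[i]]
        } else {
          NULL
        }
        walk(p[[i]], gi)
      }
    } else if (is.numeric(p)) {
      acc[[length(acc) + 1L]] <<- if (is.null(g)) p * 0 else g
    }
  }
  walk(params, grads)
  acc
}
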