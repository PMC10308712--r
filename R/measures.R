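#' Absolute cosine similarity between two embedding matrices
#'
#' Measures how orthogonal a shared embedding is to a specific embedding.
#' The default `"columns"` form is the mean absolute cosine over all
#' column pairs (one column from each matrix) across the batch, with
#' zero-norm columns excluded; each embedding dimension counts equally.
#' The `"weighted"` form is the normalized Frobenius inner product
#' `||Hc' Hs||_F / (||Hc||_F ||Hs||_F)` — the root-mean-square of the
#' column-pair cosines weighted by the product of column norms, i.e. the
#' scale-free counterpart of the orthogonality penalty (which drives
#' exactly `||Hc' Hs||_F` to zero).  The two readings differ when
#' rectified layers leave columns of very unequal magnitude; reporting
#' both gives the full picture.  Note rectified embeddings are
#' non-negative, so even two independent random embeddings have expected
#' cosines around 0.3 — values well below that indicate active
#' separation.
#'
#' @param Hc,Hs batch x d matrices.
#' @param method `"columns"` (default) or `"weighted"`.
#' @return scalar in `[0, 1]`.
#' @export
embeddingCosine <- function(Hc, Hs, method = c("columns", "weighted")) {
  method <- match.arg(method)
  M <- crossprod(Hc, Hs)
  if (method == "weighted") {
    den <- sqrt(sum(Hc^2)) * sqrt(sum(Hs^2))
    if (den < 1e-12) {
      return(0)
    }
    return(sqrt(sum(M * M)) / den)
  }
  nc <- sqrt(colSums(Hc^2))
  ns <- sqrt(colSums(Hs^2))
  den <- outer(nc, ns)
  ok <- den > 1e-12
  if (!any(ok)) {
    return(0)
  }
  mean(abs(M[ok] / den[ok]))
}

#' Multivariate linear-probe R-squared
#'
#' Fits an ordinary least-squares probe from an embedding `X` to a planted
#' latent matrix `Z` (with intercept) and returns the mean per-dimension
#' coefficient of determination.  Used to quantify how much of the planted
#' structure an embedding retains.
#'
#' @param X N x d predictor matrix (an embedding).
#' @param Z N x m target matrix (planted latents).
#' @return mean R^2 over the m target dimensions.
#' @export
linearProbeR2 <- function(X, Z) {
  Z <- as.matrix(Z)
  fit <- stats::lm.fit(cbind(1, X), Z)
  res <- as.matrix(fit$residuals)
  tss <- colSums(scale(Z, scale = FALSE)^2)
  mean(1 - colSums(res^2) / tss)
}
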