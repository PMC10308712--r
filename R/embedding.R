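#' Export a 2-D embedding of learned features
#'
#' Convenience export for visualizing fused or per-branch embeddings.
#' Delegates to an established dimensionality reduction: principal
#' components (default) or classical multidimensional scaling.  Writes a
#' TSV of 2-D coordinates plus the sample label, with a header comment
#' recording the method, seed and parameters, and returns the coordinates
#' invisibly.
#'
#' @param features N x d numeric matrix (N >= 5).
#' @param labels per-sample labels, round-tripped into the output.
#' @param path output TSV path.
#' @param method `"pca"` or `"mds"`.
#' @param seed recorded in the header (the delegated methods are
#'   deterministic; the seed is applied for forward compatibility).
#' @return invisibly, a data.frame with `dim1`, `dim2`, `label`.
#' @export
exportEmbedding <- function(features, labels, path, method = c("pca", "mds"),
                            seed = 1L) {
  method <- match.arg(method)
  assertThat(nrow(features) >= 5L, "need at least 5 samples")
  assertThat(length(labels) == nrow(features), "one label per sample")
  coords <- withSeed(seed, {
    if (method == "pca") {
      pc <- prcomp(features, rank. = 2L, center = TRUE, scale. = FALSE)
      pc$x[, 1:2, drop = FALSE]
    } else {
      cmdscale(dist(features), k = 2L)
    }
  })
  df <- data.frame(dim1 = coords[, 1L], dim2 = coords[, 2L], label = labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# method=%s seed=%d n=%d d=%d",
    method, as.integer(seed), nrow(features), ncol(features)
  ), con)
  write.table(df, con,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE
  )
  invisible(df)
}

#' Read coordinates written by [exportEmbedding()]
#'
#' @param path TSV path.
#' @return data.frame with `dim1`, `dim2`, `label`.
#' @export
readEmbedding <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}
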