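#' Save / load a model checkpoint
#'
#' Single-file, versioned serialization of a built (or trained) model:
#' weights, mapping and network configuration, and the seed it was built
#' with.
#'
#' @param model an `ssnModel`.
#' @param path checkpoint file path (RDS).
#' @return `writeModel` returns `path` invisibly; `readModel` the
#'   restored `ssnModel`.
#' @export
writeModel <- function(model, path) {
  stopifnot(inherits(model, "ssnModel"))
  obj <- list(format = "ssfuse-checkpoint", version = 1L, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- readRDS(path)
  assertThat(
    identical(obj$format, "ssfuse-checkpoint"),
    "not an ssfuse checkpoint"
  )
  assertThat(obj$version <= 1L, "checkpoint written by a newer version")
  obj$model
}
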