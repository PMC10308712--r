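#' Read a YAML run configuration
#'
#' Parses a YAML file with optional blocks `mapping`, `net`, `train`,
#' `weights` mirroring [mappingSpec()], [netConfig()], [trainConfig()] and
#' [lossWeights()], filling unspecified fields with the package defaults.
#' A template documenting every field (and the published hyper-parameter
#' search grids) ships at
#' `system.file("extdata", "config-template.yaml", package = "ssfuse")`.
#'
#' @param path YAML file path.
#' @return list with `mapping` (or NULL), `net`, `train`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  weights <- do.call(lossWeights, as.list(cfg$weights))
  trainArgs <- as.list(cfg$train)
  trainArgs$weights <- weights
  list(
    mapping = if (!is.null(cfg$mapping)) {
      do.call(mappingSpec, as.list(cfg$mapping))
    },
    net = do.call(netConfig, as.list(cfg$net)),
    train = do.call(trainConfig, trainArgs)
  )
}
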