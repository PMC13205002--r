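#' @title Run configuration
#' @description All tunable modelling constants (tissue baselines,
#'   personalization coefficients, solver resolution, fiber/cable constants,
#'   waveform, scoring options, generator settings) live in a single nested
#'   list that serializes to YAML/JSON. Every pipeline output embeds a hash
#'   of the resolved configuration.
#' @name run_config
NULL

.config_cache <- new.env(parent = emptyenv())

#' Load a run configuration
#'
#' @param path YAML (or JSON) configuration file; defaults to the packaged
#'   default configuration
#' @return nested list with class `pcsrank_config`
#' @export
load_run_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_config.yaml", package = "pcsrank")
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cfg$solver$lateral_extent_mm <- as.numeric(cfg$solver$lateral_extent_mm)
  cfg$solver$layer_cells <- as.integer(cfg$solver$layer_cells)
  class(cfg) <- c("pcsrank_config", "list")
  cfg
}

#' Default run configuration (cached)
#'
#' @return the packaged default configuration
#' @export
default_run_config <- function() {
  if (is.null(.config_cache$default))
    .config_cache$default <- load_run_config()
  .config_cache$default
}

#' Hash of a resolved configuration (provenance)
#'
#' A short deterministic digest of the serialized configuration, embedded in
#' pipeline outputs so every artifact records the settings that produced it.
#'
#' @param config a run configuration
#' @return character scalar
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small polynomial rolling hash (kept below 2^53 so arithmetic is exact);
  # avoids a digest dependency
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
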