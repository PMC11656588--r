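# recursively collapse unnamed lists of scalars (as produced by YAML/JSON
# parsers) into numeric vectors so configuration blocks match the
# constructors' expectations
simplify_cfg <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, simplify_cfg)
    scalars <- all(vapply(x, function(e) is.numeric(e) && length(e) == 1L,
                          logical(1)))
    if (is.null(names(x)) && length(x) && scalars) return(unlist(x))
  }
  x
}

apply_block <- function(constructor, block, prefix) {
  if (is.null(block)) return(constructor())
  check(is.list(block), "config: '%s' must be a mapping", prefix)
  unknown <- setdiff(names(block), names(formals(constructor)))
  if (length(unknown))
    stop(sprintf("config: unknown field '%s.%s'", prefix, unknown[1]),
         call. = FALSE)
  do.call(constructor, lapply(block, simplify_cfg))
}

#' Build a simulation configuration from a plain list
#'
#' Validates the top-level keys (\code{milk_model}, \code{reproduction},
#' \code{economics}) and every field inside them against the module
#' constructors; unknown fields raise an error naming the offending path.
#' Omitted blocks and fields take their defaults.
#'
#' @param raw named list, e.g. parsed from YAML or JSON.
#' @return a [sim_config()].
#' @export
sim_config_from_list <- function(raw) {
  check(is.list(raw), "config: top level must be a mapping")
  allowed <- c("milk_model", "reproduction", "economics")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop(sprintf("config: unknown field '%s'", unknown[1]), call. = FALSE)
  sim_config(
    milk_model = apply_block(milk_config, raw$milk_model, "milk_model"),
    reproduction = apply_block(repro_config, raw$reproduction, "reproduction"),
    economics = apply_block(econ_config, raw$economics, "economics"))
}

#' Load a simulation configuration file
#'
#' Reads a YAML (.yaml/.yml) or JSON (.json) configuration file with the
#' blocks \code{milk_model}, \code{reproduction} and \code{economics} and
#' validates it via [sim_config_from_list()]. A commented example lives at
#' \code{system.file("extdata", "default_config.yaml", package = "cowspace")}.
#'
#' @param path file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  check(file.exists(path), "read_sim_config: file not found: %s", path)
  ext <- tolower(sub(".*\\.", "", path))
  raw <- switch(ext,
                yaml = ,
                yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("read_sim_config: unsupported extension '.", ext,
                     "' (use .yaml, .yml or .json)", call. = FALSE))
  sim_config_from_list(raw)
}
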