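#' Load and validate a simulator configuration file
#'
#' Reads a YAML configuration with up to three sections — `geometry`,
#' `params` and `modifiers` — validates it against the schema (unknown keys
#' are rejected with their full path), fills all omitted values with the
#' package defaults, and returns the constructed objects. An empty file
#' yields the all-defaults configuration.
#'
#' @param path Path to a YAML file.
#' @return Object of class `soce_config`: list with `geometry`
#'   ([socm_geometry()]), `params` ([socm_params()]), `modifiers`
#'   ([oxidation_modifiers()]) and `hash` (reproducible configuration hash).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build_config(raw)
}

build_config <- function(raw) {
  known <- list(
    geometry = names(formals(socm_geometry)),
    params = names(formals(socm_params)),
    modifiers = names(formals(oxidation_modifiers))
  )
  bad_top <- setdiff(names(raw), names(known))
  if (length(bad_top))
    stop("unknown configuration section: ", bad_top[1])
  for (sec in names(known)) {
    extra <- setdiff(names(raw[[sec]]), known[[sec]])
    if (length(extra))
      stop("unknown configuration key: ", sec, ".", extra[1])
  }
  geometry <- do.call(socm_geometry, raw$geometry %||% list())
  params <- do.call(socm_params, raw$params %||% list())
  modifiers <- do.call(oxidation_modifiers, raw$modifiers %||% list())
  cfg <- list(geometry = geometry, params = params, modifiers = modifiers)
  cfg$hash <- config_hash(list(
    geometry = raw$geometry %||% list(),
    params = unclass(params), modifiers = unclass(modifiers)))
  class(cfg) <- "soce_config"
  cfg
}

#' Save a configuration to YAML
#'
#' Writes the `params` and `modifiers` values and the geometry construction
#' arguments, so that [load_config()] of the result reproduces the
#' configuration exactly.
#'
#' @param config A `soce_config` object from [load_config()], or a list
#'   with elements among `geometry`, `params`, `modifiers`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  g <- config$geometry
  out <- list(
    geometry = list(domain_side = g$domain_side, lattice_spacing = g$h,
                    n_junctions = nrow(g$junctions),
                    junction_radius = if (nrow(g$junctions))
                      g$junctions$radius[1] else 0.1),
    params = unclass(config$params),
    modifiers = unclass(config$modifiers)
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.soce_config <- function(x, ...) {
  cat("Simulator configuration (hash ", x$hash, ")\n", sep = "")
  print(x$geometry); print(x$params); print(x$modifiers)
  invisible(x)
}

# One metadata record per CLI run: provenance of every data output.
write_run_metadata <- function(out_dir, command, seed, config_hash = NULL,
                               files = character(0)) {
  meta <- list(
    tool = "socetools",
    version = as.character(utils::packageVersion("socetools")),
    command = command,
    config_hash = config_hash,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(files)
  )
  path <- file.path(out_dir, "run_meta.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
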