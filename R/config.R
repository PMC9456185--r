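#' Read and validate a run configuration (JSON or YAML)
#'
#' A run configuration mirrors the arguments of the analysis functions
#' (paths, selections, thresholds, temperatures, seeds). Unknown keys are
#' rejected rather than silently ignored, and any key ending in `_path` /
#' named `path` must point at an existing file, so a typo fails before any
#' computation starts.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @param known Character vector of permitted keys; default the union of
#'   argument names used across the package's analysis entry points.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path, known = hg_config_keys) {
  if (!file.exists(path)) hg_abort(sprintf("Config not found: %s", path), "io")
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = read_yaml_config(path),
    hg_abort(sprintf("Unsupported config format '.%s' (use JSON or YAML).", ext),
             "input")
  )
  if (!is.list(cfg) || is.null(names(cfg)) || any(names(cfg) == "")) {
    hg_abort("Config must be a mapping of named keys.", "schema")
  }
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    hg_abort(sprintf("Unknown config key(s): %s.",
                     paste0("`", unknown, "`", collapse = ", ")), "schema")
  }
  is_path_key <- grepl("(^|_)path$", names(cfg))
  for (k in names(cfg)[is_path_key]) {
    if (!file.exists(cfg[[k]])) {
      hg_abort(sprintf("Config key `%s` points at a missing file: %s.",
                       k, cfg[[k]]), "io")
    }
  }
  cfg
}

read_yaml_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    hg_abort("YAML configs need the `yaml` package; use JSON instead.", "input")
  }
  yaml::read_yaml(path)
}

hg_config_keys <- c(
  "path", "topology_path", "out_path", "format",
  "r2_threshold", "reference_t", "gas_constant", "temperature",
  "cutoff", "reference_frame", "selection",
  "x_bin", "y_bin", "threshold",
  "dr", "r_max", "smooth_window", "bulk_density",
  "g_exp", "sem_mode", "seed", "log_level"
)
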