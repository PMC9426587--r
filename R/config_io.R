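#' Load a model configuration file
#'
#' Reads a YAML or JSON configuration with a flat key namespace mirroring the
#' field names of [fixed_parameters()], [free_parameters()] and [run_config()],
#' validates every value against its documented bound, fills defaults for
#' omitted fields and records the provenance (file vs default) of each field.
#' Free parameters default to the published optima for the configured variant.
#'
#' Out-of-range values are rejected with a named-field error, never clamped.
#'
#' @param path path to a `.yaml`, `.yml` or `.json` file.
#' @return a list with elements `fixed` (`trd_fixed`), `free` (`trd_free`),
#'   `config` (`trd_config`) and `provenance` (named character vector,
#'   `"file"` or `"default"` per key).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format '.", ext, "' (use YAML or JSON)")
  )
  if (!is.list(raw)) stop("config must parse to a key-value mapping")
  if (is.null(names(raw)) || any(names(raw) == "")) {
    stop("every config entry must be named")
  }
  # YAML/JSON readers return whole numbers as integers; model fields are doubles
  raw <- lapply(raw, function(x) if (is.integer(x)) as.double(x) else x)

  fixed_names <- names(fixed_parameters(.validate = FALSE))
  free_names  <- colnames(free_parameter_bounds())
  run_names   <- names(run_config())

  bad <- setdiff(names(raw), c(fixed_names, free_names, run_names))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }

  take <- function(keys) raw[intersect(names(raw), keys)]
  fixed <- do.call(fixed_parameters, take(fixed_names))
  config <- do.call(run_config, take(run_names))

  free_given <- take(free_names)
  free_def <- default_optimized_parameters(config$variant)
  free_all <- utils::modifyList(unclass(free_def), free_given)
  free <- do.call(free_parameters, free_all)

  all_names <- c(fixed_names, free_names, run_names)
  provenance <- stats::setNames(
    ifelse(all_names %in% names(raw), "file", "default"), all_names
  )
  list(fixed = fixed, free = free, config = config, provenance = provenance)
}

#' Serialize a model configuration
#'
#' Writes the full resolved parameter set to YAML or JSON (by file extension)
#' with enough precision that [load_config()] reproduces every field exactly.
#'
#' @param fixed,free,config parameter objects as returned by [load_config()].
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
serialize_config <- function(fixed, free, config, path) {
  flat <- c(unclass(fixed), unclass(free), unclass(config))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(flat, path, precision = 17L)
  } else if (ext == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else {
    stop("unsupported config format '.", ext, "' (use YAML or JSON)")
  }
  invisible(path)
}
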