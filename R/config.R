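# Configuration files: YAML or JSON, detected by extension. A config is a
# nested list mirroring the package's builder functions; absent keys take
# the package defaults, unknown keys are rejected with their key path so a
# typo can never silently fall back to a default.

run_config_defaults <- function() {
  list(
    variant = "as_printed",
    weights = list(w_O2 = 1, w_CO2 = 1),
    constants = list(v_d = 150, s_O2 = 1.5, s_CO2 = 0.8),
    bounds = list(T = c(0.132, 0.134), t = c(0.008, 0.012), x = c(5, 100),
                  v_t = c(600, 1000), f_I_O2 = c(0.13, 0.19),
                  f_I_CO2 = c(2e-04, 6e-04)),
    annealing = list(initial_temperature = NULL, cooling_factor = 0.92,
                     steps_per_temperature = 100, min_temperature = 1e-3,
                     neighbor_scale = 0.15, max_evaluations = NULL),
    scheme = list(scheme = "global", per_cycle_budget = 300,
                  rate_limit = NULL, convergence_tol = 1e-4, patience = 3,
                  max_cycles = 40,
                  nominal_start = list(T = 0.133, t = 0.01, x = 30, v_t = 800,
                                       f_I_O2 = 0.16, f_I_CO2 = 4e-04)),
    sweep = list(q_max_values = seq(700, 1100, by = 100),
                 schemes = c("global", "sequential"), seeds = 1L),
    output_dir = ".",
    seed = 1L,
    log_level = "info"
  )
}

# Keys whose value may legitimately be NULL (and so can't be distinguished
# from "absent" by modifyList): handled explicitly below.
nullable_keys <- c("annealing.initial_temperature", "annealing.max_evaluations",
                   "scheme.rate_limit")

check_known_keys <- function(user, ref, path = character()) {
  if (!is.list(user)) return(invisible(NULL))
  for (nm in names(user)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(ref)) {
      stop_config(sprintf("unknown configuration key `%s`", here))
    }
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(user[[nm]])) {
      check_known_keys(user[[nm]], ref[[nm]], c(path, nm))
    }
  }
  invisible(NULL)
}

merge_config <- function(user, ref, path = character()) {
  out <- ref
  for (nm in names(user)) {
    here <- paste(c(path, nm), collapse = ".")
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(user[[nm]])) {
      out[[nm]] <- merge_config(user[[nm]], ref[[nm]], c(path, nm))
    } else if (is.null(user[[nm]])) {
      if (here %in% nullable_keys) out[nm] <- list(NULL)
    } else {
      out[[nm]] <- user[[nm]]
    }
  }
  out
}

#' Load and validate a run configuration
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration file,
#' rejects unknown keys (naming the offending key path), fills every
#' absent key with the package default, and validates the result by
#' constructing the corresponding parameter objects. An empty file yields
#' the full default configuration.
#'
#' @param path Path to the configuration file.
#' @return A `run_config`: validated nested list with fields `variant`,
#'   `weights`, `constants`, `bounds`, `annealing`, `scheme`, `sweep`,
#'   `output_dir`, `seed`, `log_level`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml", "")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_config(sprintf("unsupported config extension `.%s` (use YAML or JSON)", ext))
  }
  resolve_config(raw)
}

#' Resolve a raw configuration list against the defaults
#'
#' @param raw Nested list as read from a config file; `NULL` or empty
#'   gives the defaults.
#' @return A validated `run_config`.
#' @export
resolve_config <- function(raw = NULL) {
  ref <- run_config_defaults()
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop_config("configuration must be a mapping of keys to values")
  check_known_keys(raw, ref)
  rc <- merge_config(raw, ref)
  # validate by construction; errors surface with their own messages
  config_constants(rc)
  config_bounds(rc)
  config_annealing(rc)
  config_scheme(rc)
  if (!rc$variant %in% MODEL_VARIANTS) {
    stop_config(sprintf("variant must be one of: %s", paste(MODEL_VARIANTS, collapse = ", ")))
  }
  if (!rc$log_level %in% c("debug", "info", "warn", "error")) {
    stop_config("log_level must be one of debug, info, warn, error")
  }
  structure(rc, class = "run_config")
}

config_constants <- function(rc) do.call(model_constants, rc$constants)

config_bounds <- function(rc) {
  b <- rc$bounds
  default_bounds(x_range = b$x, T_range = b$T, t_range = b$t,
                 v_t_range = b$v_t, f_I_O2_range = b$f_I_O2,
                 f_I_CO2_range = b$f_I_CO2)
}

config_annealing <- function(rc, seed = NULL) {
  a <- rc$annealing
  anneal_config(initial_temperature = a$initial_temperature,
                cooling_factor = a$cooling_factor,
                steps_per_temperature = a$steps_per_temperature,
                min_temperature = a$min_temperature,
                neighbor_scale = a$neighbor_scale,
                max_evaluations = a$max_evaluations,
                seed = seed %||% rc$seed)
}

config_scheme <- function(rc, scheme = NULL, seed = NULL) {
  s <- rc$scheme
  scheme_config(scheme = scheme %||% s$scheme,
                variant = rc$variant,
                weights = c(rc$weights$w_O2, rc$weights$w_CO2),
                annealing = config_annealing(rc, seed),
                per_cycle_budget = s$per_cycle_budget,
                rate_limit = s$rate_limit,
                convergence_tol = s$convergence_tol,
                patience = s$patience,
                max_cycles = s$max_cycles,
                nominal_start = do.call(rescuer_params, s$nominal_start))
}

config_sweep <- function(rc, seed = NULL) {
  sweep_config(q_max_values = rc$sweep$q_max_values,
               schemes = rc$sweep$schemes,
               scheme_config = config_scheme(rc, seed = seed),
               seeds = if (is.null(seed)) rc$sweep$seeds else as.integer(seed),
               bounds = config_bounds(rc),
               constants = config_constants(rc))
}

#' Write a resolved configuration to a file
#'
#' Serializes a `run_config` to JSON (or YAML by extension) such that
#' [load_config()] on the written file reproduces an equivalent
#' configuration.
#'
#' @param config A `run_config` from [load_config()] or [resolve_config()].
#' @param path Destination path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "run_config")) stop_config("config must be a run_config")
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else {
    stop_config("config can be written as .json, .yaml or .yml only")
  }
  invisible(path)
}
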