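# Tabular outputs. CSVs are RFC-4180 with a header row and '.' decimal
# separator; doubles are written with round-trip precision so re-reading a
# file reproduces every value exactly.

summary_columns <- c("scheme", "q_max", "seed", "cycles_run", "converged",
                     "final_x", "final_T", "final_t", "final_vt",
                     "final_fio2", "final_fico2",
                     "final_D_O2", "final_D_CO2", "final_D_total")

trajectory_columns <- c("scheme", "q_max", "seed", "cycle", "phase",
                        "x", "T", "t", "compression_speed", "v_t",
                        "f_I_O2", "f_I_CO2", "Q_bar", "D_O2", "D_CO2", "D_total")

empty_typed_tbl <- function(cols) {
  types <- list(scheme = character(), phase = character(),
                converged = logical(), seed = integer(),
                cycles_run = integer(), cycle = integer())
  as_tibble(setNames(lapply(cols, function(nm) types[[nm]] %||% numeric()), cols))
}

#' Write sweep outputs to a directory
#'
#' Emits `summary.csv` (one row per run: final parameters and deliveries),
#' `trajectory.csv` (one row per recorded phase of every run), and — when
#' a configuration is supplied — `config.json`, the fully resolved
#' configuration, next to them for provenance. An empty result writes
#' headers-only CSVs.
#'
#' @param result A `cpr_sweep` from [run_sweep()], or `NULL` for an empty
#'   result.
#' @param dir Output directory; created if missing.
#' @param config Optional `run_config` to archive alongside the tables.
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, dir, config = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) {
      abort(sprintf("cannot create output directory `%s`", dir),
            class = c("cproptim_io_error", "cproptim_error"))
    }
  }
  if (is.null(result)) {
    summary <- empty_typed_tbl(summary_columns)
    traj <- empty_typed_tbl(trajectory_columns)
  } else {
    if (!inherits(result, "cpr_sweep")) {
      stop_domain("result must be a cpr_sweep or NULL")
    }
    summary <- result$summary |>
      dplyr::rename(final_x = "x", final_T = "T", final_t = "t",
                    final_vt = "v_t", final_fio2 = "f_I_O2",
                    final_fico2 = "f_I_CO2", final_D_O2 = "D_O2",
                    final_D_CO2 = "D_CO2", final_D_total = "D_total") |>
      select(all_of(summary_columns))
    traj <- trajectory_report(result) |> select(all_of(trajectory_columns))
  }
  files <- c(summary = file.path(dir, "summary.csv"),
             trajectory = file.path(dir, "trajectory.csv"))
  readr::write_csv(summary, files[["summary"]])
  readr::write_csv(traj, files[["trajectory"]])
  if (!is.null(config)) {
    files <- c(files, config = file.path(dir, "config.json"))
    write_config(config, files[["config"]])
  }
  invisible(files)
}
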