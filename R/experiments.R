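# Patient-group sweep and trajectory reporting: run one or both schemes
# across a span of patient maximum flows and tabulate the optimized
# parameters, deliveries and per-cycle series.

#' Generate a synthetic patient cohort
#'
#' Patients differ only in their maximum achievable blood flow `q_max`,
#' drawn uniformly over `q_range`. The default range (700--1100 mL/min)
#' spans the patient groups the optimization experiments cover.
#'
#' @param n Number of patients (>= 1).
#' @param q_range Length-2 `(low, high)` in mL/min, `low <= high`.
#' @param seed Integer seed; draws are reproducible and the caller's RNG
#'   state is untouched.
#' @return Tibble with columns `patient_id`, `q_max`.
#' @export
#' @examples
#' generate_patient_cohort(5, seed = 42)
generate_patient_cohort <- function(n, q_range = q_max_range("sweep"), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop_domain("n must be >= 1")
  if (length(q_range) != 2 || any(!is.finite(q_range)) || q_range[1] > q_range[2]) {
    stop_domain("q_range must be finite (low, high) with low <= high")
  }
  if (any(q_range <= 0)) stop_domain("q_max values must be strictly positive")
  withr::with_seed(as.integer(seed), {
    tibble(patient_id = seq_len(n),
           q_max = runif(n, q_range[1], q_range[2]))
  })
}

#' Sweep configuration
#'
#' @param q_max_values Patient maximum flows to sweep, mL/min; default the
#'   patient-group grid 700, 800, ..., 1100.
#' @param schemes Subset of `c("global", "sequential")`.
#' @param scheme_config A [scheme_config()] used for every run (its
#'   `scheme` field is overridden per run).
#' @param seeds Integer vector of replicate seeds (>= 1 seed).
#' @param bounds Bounds tibble from [default_bounds()].
#' @param constants Model constants from [model_constants()].
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(q_max_values = seq(700, 1100, by = 100),
                         schemes = c("global", "sequential"),
                         scheme_config = cproptim::scheme_config(),
                         seeds = 1L,
                         bounds = default_bounds(),
                         constants = model_constants()) {
  if (length(q_max_values) == 0 || any(q_max_values <= 0)) {
    stop_config("q_max_values must be a nonempty vector of positive flows")
  }
  schemes <- match.arg(schemes, c("global", "sequential"), several.ok = TRUE)
  if (length(seeds) == 0) stop_config("at least one seed is required")
  structure(list(q_max_values = as.numeric(q_max_values),
                 schemes = schemes,
                 scheme_config = scheme_config,
                 seeds = as.integer(seeds),
                 bounds = check_bounds_tbl(bounds, required = RESCUER_PARAMS),
                 constants = as_constants(constants)),
            class = "sweep_config")
}

#' Run the patient-group sweep
#'
#' Optimizes blood gas delivery for every combination of patient `q_max`,
#' scheme and replicate seed, then tabulates the final optima. The summary
#' is checked for the model's structural property that optimized delivery
#' increases with `q_max` within each scheme; a violation aborts with
#' context, since it indicates an optimizer failure.
#'
#' @param config A [sweep_config()].
#' @return A `cpr_sweep`: list with `outcomes` (list of `cpr_outcome`),
#'   `summary` (one row per run), `trajectories` (all per-cycle records)
#'   and the `config`.
#' @export
#' @examples
#' \donttest{
#' sw <- run_sweep(sweep_config(q_max_values = c(700, 900), schemes = "global"))
#' sw$summary
#' }
run_sweep <- function(config) {
  if (!inherits(config, "sweep_config")) stop_config("config must come from sweep_config()")
  runs <- tidyr::expand_grid(scheme = config$schemes,
                             q_max = config$q_max_values,
                             seed = config$seeds)
  outcomes <- purrr::pmap(runs, function(scheme, q_max, seed) {
    cfg <- config$scheme_config
    cfg$scheme <- scheme
    cfg$annealing$seed <- as.integer(seed)
    fn <- if (scheme == "global") global_optimize else sequential_optimize
    tryCatch(
      fn(q_max, config$bounds, cfg, config$constants),
      cproptim_error = function(e) {
        abort(sprintf("sweep run failed (scheme=%s, q_max=%g, seed=%d): %s",
                      scheme, q_max, seed, conditionMessage(e)),
              class = class(e), parent = e)
      })
  })

  summary <- purrr::map2(outcomes, seq_len(nrow(runs)), function(o, i) {
    glance(o) |> mutate(seed = runs$seed[i], .after = "q_max")
  }) |>
    bind_rows() |>
    arrange(.data$scheme, .data$q_max, .data$seed)

  for (sch in config$schemes) {
    s <- summary |>
      filter(.data$scheme == sch) |>
      group_by(.data$q_max) |>
      summarise(D = max(.data$D_total), .groups = "drop") |>
      arrange(.data$q_max)
    if (nrow(s) > 1 && any(diff(s$D) <= 0)) {
      abort(sprintf(
        "optimized delivery is not strictly increasing in q_max for the %s scheme", sch),
        class = c("cproptim_sweep_error", "cproptim_error"))
    }
  }

  trajectories <- purrr::map2(outcomes, seq_len(nrow(runs)), function(o, i) {
    tidy(o) |> mutate(seed = runs$seed[i], .after = "scheme")
  }) |> bind_rows()

  structure(list(outcomes = outcomes, summary = summary,
                 trajectories = trajectories, config = config),
            class = "cpr_sweep")
}

#' Per-cycle trajectory report
#'
#' Flattens a sweep into the per-cycle series of the quantities of
#' interest: ratio `x`, ventilation time `T`, compression time `t` and
#' speed `1/t`, tidal volume, inspired fractions, mean flow and the three
#' deliveries — one row per recorded phase of every run.
#'
#' @param result A `cpr_sweep` from [run_sweep()].
#' @return Tibble with columns `scheme`, `q_max`, `seed`, `cycle`, `phase`,
#'   `x`, `T`, `t`, `compression_speed`, `v_t`, `f_I_O2`, `f_I_CO2`,
#'   `Q_bar`, `D_O2`, `D_CO2`, `D_total`.
#' @export
trajectory_report <- function(result) {
  if (!inherits(result, "cpr_sweep")) stop_domain("result must be a cpr_sweep")
  if (length(result$outcomes) == 0) stop_domain("sweep result is empty")
  result$trajectories |>
    mutate(compression_speed = 1 / .data$t) |>
    select(all_of(c("scheme", "q_max", "seed", "cycle", "phase",
                    "x", "T", "t", "compression_speed", "v_t",
                    "f_I_O2", "f_I_CO2", "Q_bar", "D_O2", "D_CO2", "D_total")))
}

#' Qualitative trend report across CPR cycles
#'
#' Records, per sequential run, whether the trajectory shows the
#' qualitative patterns of interest: ratio `x` non-increasing after the
#' first cycle, compression speed `1/t` non-decreasing, and ventilation
#' time `T` staying within its clinical bounds. These are reported, never
#' asserted: a static objective gives the optimizers no reason to move
#' gradually, so the first two patterns are expected only when a per-cycle
#' `rate_limit` shapes the trajectory (see the vignette).
#'
#' @param result A `cpr_sweep`.
#' @return Tibble with one row per (scheme, q_max, seed) and logical
#'   columns `ratio_non_increasing`, `speed_non_decreasing`,
#'   `vent_time_in_bounds`.
#' @export
qualitative_trends <- function(result) {
  rep <- trajectory_report(result)
  tol <- 1e-9
  b <- result$config$bounds
  T_lo <- b$lower[b$parameter == "T"]
  T_hi <- b$upper[b$parameter == "T"]
  rep |>
    filter(.data$phase %in% c("ratio_step", "others_step", "global_step")) |>
    group_by(.data$scheme, .data$q_max, .data$seed) |>
    summarise(
      ratio_non_increasing = all(diff(.data$x[.data$cycle > 1]) <= tol) ||
        sum(.data$cycle > 1) < 2,
      speed_non_decreasing = all(diff(.data$compression_speed) >= -tol),
      vent_time_in_bounds = all(.data$T >= T_lo - tol & .data$T <= T_hi + tol),
      .groups = "drop")
}

#' @export
print.cpr_sweep <- function(x, ...) {
  cat(sprintf("CPR optimization sweep: %d runs (%s; q_max %s mL/min)\n",
              length(x$outcomes), paste(x$config$schemes, collapse = " + "),
              paste(range(x$config$q_max_values), collapse = "-")))
  print(x$summary)
  invisible(x)
}

#' Tidy a sweep into its per-run summary
#'
#' @param x A `cpr_sweep`.
#' @param ... Unused.
#' @return The summary tibble, one row per (scheme, q_max, seed).
#' @export
tidy.cpr_sweep <- function(x, ...) x$summary

#' One-row summary of a sweep
#'
#' @param x A `cpr_sweep`.
#' @param ... Unused.
#' @return One-row tibble with run counts and the delivery range.
#' @export
glance.cpr_sweep <- function(x, ...) {
  tibble(n_runs = length(x$outcomes),
         n_schemes = length(x$config$schemes),
         n_patients = length(x$config$q_max_values),
         min_D_total = min(x$summary$D_total),
         max_D_total = max(x$summary$D_total),
         all_converged = all(x$summary$converged))
}

#' Plot optimized delivery against patient maximum flow
#'
#' @param object A `cpr_sweep`.
#' @param ... Unused.
#' @return A ggplot of final `D_total` versus `q_max`, one line per scheme.
#' @export
autoplot.cpr_sweep <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$q_max, y = .data$D_total,
                               colour = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(q[max] ~ "(mL/min)"),
                  y = expression(D[total] ~ "(mL/min)"),
                  title = "Optimized total blood gas delivery by patient group") +
    ggplot2::theme_minimal()
}

#' Plot a per-cycle parameter series from a sweep
#'
#' @param result A `cpr_sweep`.
#' @param parameter One of `"x"`, `"T"`, `"compression_speed"`, `"v_t"`,
#'   `"D_total"`.
#' @return A ggplot of the series against cycle, one line per `q_max`.
#' @export
plot_trajectory <- function(result, parameter = c("x", "T", "compression_speed",
                                                  "v_t", "D_total")) {
  parameter <- match.arg(parameter)
  rep <- trajectory_report(result)
  ggplot2::ggplot(rep,
                  ggplot2::aes(x = .data$cycle, y = .data[[parameter]],
                               colour = factor(.data$q_max),
                               linetype = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "CPR cycle", y = parameter, colour = "q_max") +
    ggplot2::theme_minimal()
}
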