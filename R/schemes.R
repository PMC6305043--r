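# The two optimization protocols over the rescuer-dependent parameters at
# fixed patient q_max: "global" anneals all six parameters at once;
# "sequential" alternates, per CPR cycle, between the compression-to-
# ventilation ratio x and the remaining five parameters, warm-starting each
# cycle at the previous best.

# Scalar fast path of the model objective: plain arithmetic, no tibbles.
# Returns NA on infeasibility so the annealer rejects the proposal.
objective_value <- function(q_max, T, t, x, v_t, f_I_O2, f_I_CO2,
                            k, variant, w_O2, w_CO2) {
  if (t <= 0 || v_t <= k$v_d) return(NA_real_)
  den_base <- (T / t + x) * (v_t - k$v_d)
  if (variant == "explicit_R") {
    cycle <- x * t + T
    if (cycle <= 0) return(NA_real_)
    Q_bar <- q_max * x / (T / t + x)
    va <- (v_t - k$v_d) / cycle
    den_co2 <- va - Q_bar * k$s_CO2
    if (den_co2 <= 0) return(NA_real_)
    f_A_O2 <- va * f_I_O2 / (va + Q_bar * k$s_O2)
    f_A_CO2 <- va * f_I_CO2 / den_co2
    D_O2 <- Q_bar * k$s_O2 * f_A_O2
    D_CO2 <- Q_bar * k$s_CO2 * f_A_CO2
  } else {
    den_co2 <- den_base - t * x * q_max * k$s_CO2
    if (den_co2 <= 0) return(NA_real_)
    if (variant == "as_printed") {
      num <- q_max * k$s_O2 * x * (v_t - k$v_d) * f_I_O2
      D_O2 <- num / (den_base + t * x * q_max * k$s_O2)
      D_CO2 <- num / den_co2
    } else {
      D_O2 <- q_max * k$s_O2 * x * (v_t - k$v_d) * f_I_O2 /
        (den_base + t * x * q_max * k$s_O2)
      D_CO2 <- q_max * k$s_CO2 * x * (v_t - k$v_d) * f_I_CO2 / den_co2
    }
  }
  w_O2 * D_O2 + w_CO2 * D_CO2
}

# Build a minimization objective over `free` parameters with the rest fixed.
delivery_objective <- function(q_max, fixed, free, constants, variant, weights) {
  k <- as_constants(constants)
  full <- unlist(fixed[RESCUER_PARAMS])
  function(par) {
    full[free] <- par
    v <- objective_value(q_max, full[["T"]], full[["t"]], full[["x"]],
                         full[["v_t"]], full[["f_I_O2"]], full[["f_I_CO2"]],
                         k, variant, weights[[1]], weights[[2]])
    if (is.na(v)) NA_real_ else -v
  }
}

#' Optimization scheme configuration
#'
#' @param scheme `"global"` (all six rescuer parameters in one annealing
#'   run) or `"sequential"` (per-CPR-cycle alternation between the ratio
#'   `x` and the remaining parameters).
#' @param variant Model formula variant, as in [blood_gas_delivery()].
#' @param weights Length-2 nonnegative weights `(w_O2, w_CO2)` on the two
#'   deliveries; unit weights give total delivery.
#' @param annealing An [anneal_config()] providing schedule, proposal and
#'   seed settings.
#' @param per_cycle_budget Proposals allotted to each annealing sub-run of
#'   a sequential cycle.
#' @param rate_limit Optional maximum fractional change (of bound width)
#'   of any parameter per cycle, in (0, 1]; `NULL` (default) disables the
#'   limit. With the limit off each cycle may move anywhere in the box;
#'   with it on, trajectories change gradually.
#' @param convergence_tol Relative improvement of best delivery below which
#'   a cycle counts as converged (> 0).
#' @param patience Number of consecutive sub-tolerance cycles required to
#'   stop (>= 1).
#' @param max_cycles Cap on sequential CPR cycles (>= 1).
#' @param nominal_start Optional [rescuer_params()] starting point; `NULL`
#'   uses the nominal midpoint values with ratio 30, clamped into the
#'   bounds box if needed.
#' @return A list of class `scheme_config`.
#' @export
scheme_config <- function(scheme = c("global", "sequential"),
                          variant = c("as_printed", "corrected_co2", "explicit_R"),
                          weights = c(1, 1),
                          annealing = anneal_config(),
                          per_cycle_budget = 300,
                          rate_limit = NULL,
                          convergence_tol = 1e-4,
                          patience = 3,
                          max_cycles = 40,
                          nominal_start = NULL) {
  scheme <- match.arg(scheme)
  variant <- match.arg(variant)
  if (length(weights) != 2 || any(weights < 0)) {
    stop_config("weights must be two nonnegative numbers (w_O2, w_CO2)")
  }
  if (!inherits(annealing, "anneal_config")) {
    stop_config("annealing must come from anneal_config()")
  }
  if (convergence_tol <= 0) stop_config("convergence_tol must be > 0")
  if (max_cycles < 1) stop_config("max_cycles must be >= 1")
  if (patience < 1) stop_config("patience must be >= 1")
  if (per_cycle_budget < 1) stop_config("per_cycle_budget must be >= 1")
  if (!is.null(rate_limit) && (rate_limit <= 0 || rate_limit > 1)) {
    stop_config("rate_limit must be NULL or in (0, 1]")
  }
  if (!is.null(nominal_start)) nominal_start <- as_rescuer(nominal_start)
  structure(list(scheme = scheme, variant = variant,
                 weights = as.numeric(weights), annealing = annealing,
                 per_cycle_budget = as.integer(per_cycle_budget),
                 rate_limit = rate_limit,
                 convergence_tol = convergence_tol,
                 patience = as.integer(patience),
                 max_cycles = as.integer(max_cycles),
                 nominal_start = nominal_start),
            class = "scheme_config")
}

resolve_start <- function(config, bounds) {
  b <- check_bounds_tbl(bounds, required = RESCUER_PARAMS)
  start <- config$nominal_start %||% unclass(rescuer_params())
  start <- unlist(start[RESCUER_PARAMS])
  idx <- match(names(start), b$parameter)
  pmin(pmax(start, b$lower[idx]), b$upper[idx])
}

check_start_feasible <- function(q_max, start, constants, variant, bounds) {
  viol <- validate_domain(q_max, as.list(start), constants, variant, bounds)
  if (nrow(viol) > 0) {
    stop_infeasible(paste0("starting point is infeasible: ",
                           paste(viol$message, collapse = "; ")))
  }
}

snapshot_record <- function(q_max, par, constants, variant, cycle, phase) {
  snap <- blood_gas_delivery(q_max, as.list(par), constants, variant)
  mutate(as_tibble(snap), cycle = cycle, phase = phase, .before = 1)
}

new_outcome <- function(scheme, q_max, trajectory, converged, cycles_run, config) {
  structure(list(scheme = scheme, q_max = q_max,
                 trajectory = trajectory,
                 final = trajectory[nrow(trajectory), ],
                 converged = converged, cycles_run = cycles_run,
                 config = config),
            class = "cpr_outcome")
}

#' Global optimization of blood gas delivery
#'
#' One simulated-annealing run over all six rescuer parameters at fixed
#' patient `q_max`, maximizing the weighted total delivery. The trajectory
#' records the best parameter set after each temperature level.
#'
#' @param patient Patient parameters ([patient_params()] or bare `q_max`).
#' @param bounds Bounds tibble from [default_bounds()].
#' @param config A [scheme_config()].
#' @param constants Model constants from [model_constants()].
#' @return A `cpr_outcome`: scheme tag, `q_max`, per-record `trajectory`
#'   tibble, `final` record, `converged` flag and `cycles_run`.
#' @export
#' @examples
#' \donttest{
#' out <- global_optimize(patient_params(900))
#' glance(out)
#' }
global_optimize <- function(patient, bounds = default_bounds(),
                            config = scheme_config("global"),
                            constants = model_constants()) {
  p <- as_patient(patient)
  b <- check_bounds_tbl(bounds, required = RESCUER_PARAMS)
  start <- resolve_start(config, b)
  check_start_feasible(p$q_max, start, constants, config$variant, b)
  obj <- delivery_objective(p$q_max, as.list(start), RESCUER_PARAMS,
                            constants, config$variant, config$weights)
  res <- anneal(obj, b[b$parameter %in% RESCUER_PARAMS, ], config$annealing, start)
  traj <- purrr::map2(
    seq_len(nrow(res$temperature_trace)),
    seq_len(nrow(res$temperature_trace)),
    function(i, cycle) {
      par <- unlist(res$temperature_trace[i, RESCUER_PARAMS])
      snapshot_record(p$q_max, par, constants, config$variant, cycle, "global_step")
    }) |> bind_rows()
  new_outcome("global", p$q_max, traj, TRUE, nrow(traj), config)
}

#' Sequential per-CPR-cycle optimization
#'
#' Implements the per-cycle alternating protocol: start from nominal
#' values; in each CPR cycle first anneal the compression-to-ventilation
#' ratio `x` with everything else fixed (the rescuer then performs the
#' cycle at that ratio — the `ratio_step` record), then anneal the
#' remaining rescuer parameters with `x` fixed (the `others_step` record);
#' warm-start the next cycle at the result and repeat until the best
#' delivery stops improving ([convergence_check()]) or `max_cycles` is
#' reached. Warm starting makes the per-cycle best delivery non-decreasing.
#'
#' @inheritParams global_optimize
#' @return A `cpr_outcome` with two records (`ratio_step`, `others_step`)
#'   per cycle.
#' @export
sequential_optimize <- function(patient, bounds = default_bounds(),
                                config = scheme_config("sequential"),
                                constants = model_constants()) {
  p <- as_patient(patient)
  b <- check_bounds_tbl(bounds, required = RESCUER_PARAMS)
  current <- resolve_start(config, b)
  check_start_feasible(p$q_max, current, constants, config$variant, b)

  others <- setdiff(RESCUER_PARAMS, "x")
  base_seed <- config$annealing$seed
  records <- list()
  d_by_cycle <- numeric(0)
  converged <- FALSE
  cycles <- 0L

  cycle_bounds <- function(free, ref) {
    bb <- b[match(free, b$parameter), ]
    if (!is.null(config$rate_limit)) {
      w <- bb$upper - bb$lower
      bb$lower <- pmax(bb$lower, ref[free] - config$rate_limit * w)
      bb$upper <- pmin(bb$upper, ref[free] + config$rate_limit * w)
    }
    bb
  }
  sub_anneal <- function(free, phase_seed, ref) {
    cfg <- config$annealing
    cfg$seed <- as.integer(phase_seed)
    cfg$max_evaluations <- config$per_cycle_budget
    obj <- delivery_objective(p$q_max, as.list(ref), free,
                              constants, config$variant, config$weights)
    res <- anneal(obj, cycle_bounds(free, ref), cfg, ref[free])
    ref[free] <- res$best_state
    ref
  }

  for (cycle in seq_len(config$max_cycles)) {
    cycles <- cycle
    current <- sub_anneal("x", base_seed + 101L * cycle, current)
    records[[length(records) + 1]] <-
      snapshot_record(p$q_max, current, constants, config$variant, cycle, "ratio_step")
    current <- sub_anneal(others, base_seed + 101L * cycle + 1L, current)
    rec <- snapshot_record(p$q_max, current, constants, config$variant, cycle, "others_step")
    records[[length(records) + 1]] <- rec
    d_by_cycle <- c(d_by_cycle,
                    weighted_total_delivery(rec, config$weights[1], config$weights[2]))
    if (convergence_check(d_by_cycle, config$convergence_tol, config$patience)) {
      converged <- TRUE
      break
    }
  }
  new_outcome("sequential", p$q_max, bind_rows(records), converged, cycles, config)
}

#' Convergence check on per-cycle best delivery
#'
#' Declares convergence when the relative improvement of the best delivery
#' has stayed below `tol` for each of the last `patience` cycles.
#'
#' @param trajectory Numeric vector of per-cycle best deliveries, or a
#'   trajectory tibble with `cycle` and `D_total` columns (per-cycle
#'   maximum is used).
#' @param tol Relative improvement threshold (> 0).
#' @param patience Consecutive sub-tolerance cycles required (>= 1).
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' convergence_check(c(100, 110, 110.5, 110.9), tol = 0.01, patience = 2)
convergence_check <- function(trajectory, tol, patience) {
  if (is.data.frame(trajectory)) {
    if (nrow(trajectory) == 0) stop_domain("trajectory must be nonempty")
    d <- trajectory |>
      group_by(.data$cycle) |>
      summarise(D = max(.data$D_total), .groups = "drop") |>
      arrange(.data$cycle)
    d <- d$D
  } else {
    d <- as.numeric(trajectory)
  }
  if (length(d) == 0) stop_domain("trajectory must be nonempty")
  if (length(d) < patience + 1) return(FALSE)
  improvements <- diff(d) / pmax(abs(d[-length(d)]), .Machine$double.eps)
  all(tail(improvements, patience) < tol)
}

#' @export
print.cpr_outcome <- function(x, ...) {
  cat(sprintf("CPR %s optimization, q_max = %g mL/min\n", x$scheme, x$q_max))
  cat(sprintf("  %d cycles, converged: %s\n", x$cycles_run, x$converged))
  cat(sprintf("  final D_total = %.4f mL/min (D_O2 = %.4f, D_CO2 = %.4f)\n",
              x$final$D_total, x$final$D_O2, x$final$D_CO2))
  invisible(x)
}

#' Tidy a CPR optimization outcome into its trajectory
#'
#' @param x A `cpr_outcome`.
#' @param ... Unused.
#' @return The per-record trajectory tibble with scheme and `q_max` columns.
#' @export
tidy.cpr_outcome <- function(x, ...) {
  out <- x$trajectory
  out$scheme <- x$scheme
  dplyr::relocate(out, "scheme")
}

#' One-row summary of a CPR optimization outcome
#'
#' @param x A `cpr_outcome`.
#' @param ... Unused.
#' @return One-row tibble with the scheme, patient flow, convergence state
#'   and final parameters/deliveries.
#' @export
glance.cpr_outcome <- function(x, ...) {
  f <- x$final
  tibble(scheme = x$scheme, q_max = x$q_max,
         cycles_run = x$cycles_run, converged = x$converged,
         x = f$x, T = f$T, t = f$t, v_t = f$v_t,
         f_I_O2 = f$f_I_O2, f_I_CO2 = f$f_I_CO2,
         D_O2 = f$D_O2, D_CO2 = f$D_CO2, D_total = f$D_total)
}

#' Plot the delivery trajectory of an optimization run
#'
#' @param object A `cpr_outcome`.
#' @param ... Unused.
#' @return A ggplot object of `D_total` against the record sequence.
#' @export
autoplot.cpr_outcome <- function(object, ...) {
  df <- mutate(object$trajectory, record = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$record, y = .data$D_total)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$phase)) +
    ggplot2::labs(x = "optimization record", y = "D_total (mL/min)",
                  title = sprintf("%s optimization, q_max = %g mL/min",
                                  object$scheme, object$q_max)) +
    ggplot2::theme_minimal()
}
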