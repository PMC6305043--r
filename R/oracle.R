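# Exhaustive grid search over the rescuer-parameter box. Serves as the
# deterministic ground truth the stochastic optimizers are validated
# against: the annealed optimum must not fall materially below the best
# grid point on the same box.

#' Grid specification
#'
#' @param points_per_dim Grid points per swept dimension (>= 2); endpoints
#'   are always included so corner optima sit on the grid. Zero-width
#'   dimensions collapse to a single point.
#' @param cap Maximum total number of grid evaluations allowed.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(points_per_dim = 9, cap = 1e7) {
  if (points_per_dim < 2) stop_config("points_per_dim must be >= 2")
  if (cap < 1) stop_config("cap must be >= 1")
  structure(list(points_per_dim = as.integer(points_per_dim), cap = cap),
            class = "grid_spec")
}

#' Exhaustive grid search of the delivery objective
#'
#' Evaluates the weighted total delivery at every point of a uniform,
#' endpoint-inclusive grid over the bounds box and returns the exact
#' maximum over the grid. Infeasible grid points (CO2 singularity,
#' `v_t <= v_d`) are skipped. Fully deterministic.
#'
#' @inheritParams global_optimize
#' @param grid A [grid_spec()].
#' @param variant Model formula variant.
#' @param weights Length-2 nonnegative delivery weights.
#' @return A list with `best_params` (one-row tibble), `best_value`
#'   (mL/min), `n_evaluated` and `n_feasible`.
#' @export
#' @examples
#' grid_search(patient_params(900), grid = grid_spec(points_per_dim = 3))
grid_search <- function(patient, bounds = default_bounds(), grid = grid_spec(),
                        variant = c("as_printed", "corrected_co2", "explicit_R"),
                        weights = c(1, 1), constants = model_constants()) {
  variant <- match.arg(variant)
  p <- as_patient(patient)
  b <- check_bounds_tbl(bounds, required = RESCUER_PARAMS)
  b <- b[match(RESCUER_PARAMS, b$parameter), ]
  if (!inherits(grid, "grid_spec")) stop_config("grid must come from grid_spec()")
  if (length(weights) != 2 || any(weights < 0)) {
    stop_domain("weights must be two nonnegative numbers")
  }
  k <- as_constants(constants)

  axes <- purrr::map2(b$lower, b$upper, function(lo, hi) {
    if (lo == hi) lo else seq(lo, hi, length.out = grid$points_per_dim)
  })
  names(axes) <- b$parameter
  total <- prod(lengths(axes))
  if (total > grid$cap) {
    stop_config(sprintf("grid has %g evaluations, above the cap of %g", total, grid$cap))
  }

  pts <- do.call(expand.grid, c(axes, KEEP.OUT.ATTRS = FALSE))
  out <- bgd_compute(p$q_max, pts$T, pts$t, pts$x, pts$v_t,
                     pts$f_I_O2, pts$f_I_CO2,
                     k$v_d, k$s_O2, k$s_CO2, variant)
  value <- weights[1] * out$D_O2 + weights[2] * out$D_CO2
  if (all(is.na(value))) {
    stop_infeasible("every grid point is infeasible for this configuration")
  }
  best <- which.max(value)
  best_params <- as_tibble(pts[best, , drop = FALSE])
  list(best_params = mutate(best_params, q_max = p$q_max, .before = 1),
       best_value = value[best],
       n_evaluated = as.integer(total),
       n_feasible = sum(!is.na(value)))
}
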