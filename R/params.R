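# Parameter containers. All quantities carry the model's native units
# throughout: times in minutes, volumes in mL, flows in mL/min, gas
# fractions dimensionless. No unit conversion happens anywhere in the core.

RESCUER_PARAMS <- c("T", "t", "x", "v_t", "f_I_O2", "f_I_CO2")
MODEL_VARIANTS <- c("as_printed", "corrected_co2", "explicit_R")

#' Physiological constants of the gas-exchange model
#'
#' `v_d` is the dead-space volume (mL): the part of each tidal breath that
#' never reaches the alveoli. `s_O2` and `s_CO2` are the linearized slopes
#' of the oxygen and carbon dioxide dissociation curves (mL gas per mL
#' blood per unit fraction change).
#'
#' @param v_d Dead-space volume, mL. Default 150.
#' @param s_O2 Slope of the O2 dissociation curve, mL/mL. Default 1.5.
#' @param s_CO2 Slope of the CO2 dissociation curve, mL/mL. Default 0.8.
#' @return A named list of the three constants.
#' @export
#' @examples
#' model_constants()
model_constants <- function(v_d = 150, s_O2 = 1.5, s_CO2 = 0.8) {
  for (nm in c("v_d", "s_O2", "s_CO2")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) || val <= 0) {
      stop_domain(sprintf("`%s` must be a single strictly positive number, got %s",
                          nm, deparse(val)))
    }
  }
  structure(list(v_d = v_d, s_O2 = s_O2, s_CO2 = s_CO2),
            class = "model_constants")
}

#' Rescuer-dependent CPR parameters
#'
#' The six quantities a rescuer controls: `T`, the pause for one artificial
#' ventilation (min); `t`, the duration of one full chest compression (min,
#' so `1/t` is the compression speed per minute); `x`, the
#' compression-to-ventilation ratio (compressions delivered per ventilation);
#' `v_t`, the tidal volume (mL); and the inspired O2 and CO2 fractions.
#'
#' Construction checks signs and fraction ranges only; the gas-exchange
#' requirement `v_t > v_d` is a model-domain condition checked by
#' [validate_domain()], not here.
#'
#' @param T Ventilation time, min (>= 0).
#' @param t Compression time, min (> 0).
#' @param x Compression-to-ventilation ratio (>= 0).
#' @param v_t Tidal volume, mL (> 0).
#' @param f_I_O2,f_I_CO2 Inspired gas fractions in `[0, 1]`.
#' @return A named list of the six parameters.
#' @export
#' @examples
#' rescuer_params(x = 30)
rescuer_params <- function(T = 0.133, t = 0.01, x = 30, v_t = 800,
                           f_I_O2 = 0.16, f_I_CO2 = 0.0004) {
  chk <- function(nm, val, ok, what) {
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) || !ok(val)) {
      stop_domain(sprintf("rescuer parameter `%s` must be %s, got %s",
                          nm, what, deparse(val)))
    }
  }
  chk("T", T, function(v) v >= 0, "a nonnegative time in minutes")
  chk("t", t, function(v) v > 0, "a strictly positive time in minutes")
  chk("x", x, function(v) v >= 0, "a nonnegative ratio")
  chk("v_t", v_t, function(v) v > 0, "a strictly positive volume in mL")
  chk("f_I_O2", f_I_O2, function(v) v >= 0 && v <= 1, "a fraction in [0, 1]")
  chk("f_I_CO2", f_I_CO2, function(v) v >= 0 && v <= 1, "a fraction in [0, 1]")
  structure(list(T = T, t = t, x = x, v_t = v_t,
                 f_I_O2 = f_I_O2, f_I_CO2 = f_I_CO2),
            class = "rescuer_params")
}

#' Patient-dependent parameter
#'
#' `q_max` is the patient's maximum achievable blood flow during chest
#' compressions (mL/min). Systemic and pulmonary flow are assumed balanced,
#' so one value serves both the oxygen and the carbon dioxide pathway.
#'
#' @param q_max Maximum blood flow, mL/min (> 0).
#' @return A named list with element `q_max`.
#' @export
#' @examples
#' patient_params(900)
patient_params <- function(q_max) {
  if (!is.numeric(q_max) || length(q_max) != 1 || !is.finite(q_max) || q_max <= 0) {
    stop_domain(sprintf("`q_max` must be a single strictly positive flow in mL/min, got %s",
                        deparse(q_max)))
  }
  structure(list(q_max = q_max), class = "patient_params")
}

#' Optimization bounds for the rescuer parameters
#'
#' Returns the box over which the optimizers search, one row per parameter
#' with `lower` and `upper` columns. Defaults are the published clinical
#' ranges: `T` in `[0.132, 0.134]` min, `t` in `[0.008, 0.012]` min,
#' `v_t` in `[600, 1000]` mL, `f_I_O2` in `[0.13, 0.19]`, `f_I_CO2` in
#' `[0.0002, 0.0006]`. No published range exists for the ratio `x`; the
#' default `[5, 100]` brackets conventional 15:2 and 30:2 practice and the
#' higher ratios the model favours, and is configurable.
#'
#' @param x_range Length-2 numeric, bounds for the ratio `x`.
#' @param T_range,t_range,v_t_range,f_I_O2_range,f_I_CO2_range Optional
#'   length-2 overrides of the default ranges.
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @export
#' @examples
#' default_bounds()
default_bounds <- function(x_range = c(5, 100),
                           T_range = c(0.132, 0.134),
                           t_range = c(0.008, 0.012),
                           v_t_range = c(600, 1000),
                           f_I_O2_range = c(0.13, 0.19),
                           f_I_CO2_range = c(0.0002, 0.0006)) {
  ranges <- list(T = T_range, t = t_range, x = x_range, v_t = v_t_range,
                 f_I_O2 = f_I_O2_range, f_I_CO2 = f_I_CO2_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2 || any(!is.finite(r))) {
      stop_config(sprintf("bounds for `%s` must be a finite length-2 numeric", nm))
    }
    if (r[1] > r[2]) {
      stop_config(sprintf("bounds for `%s`: lower (%g) exceeds upper (%g)", nm, r[1], r[2]))
    }
  }
  tibble(parameter = names(ranges),
         lower = map_dbl(ranges, 1),
         upper = map_dbl(ranges, 2))
}

#' Patient-group flow ranges
#'
#' Two named presets for the span of `q_max` across patient groups:
#' `"sweep"` (700--1100 mL/min), the range the optimization experiments
#' use, and `"table"` (400--1000 mL/min), the wider tabulated alternative.
#'
#' @param preset `"sweep"` or `"table"`.
#' @return Length-2 numeric `(low, high)` in mL/min.
#' @export
q_max_range <- function(preset = c("sweep", "table")) {
  preset <- match.arg(preset)
  switch(preset, sweep = c(700, 1100), table = c(400, 1000))
}

# Coerce assorted user inputs (named list, named vector, one-row data frame,
# bare number for patients) to a plain named list for the core.
as_rescuer <- function(rescuer) {
  if (inherits(rescuer, "rescuer_params")) return(unclass(rescuer))
  if (is.data.frame(rescuer)) {
    if (nrow(rescuer) != 1) stop_domain("rescuer data frame must have exactly one row")
    rescuer <- as.list(rescuer)
  }
  if (is.numeric(rescuer) && !is.null(names(rescuer))) rescuer <- as.list(rescuer)
  if (!is.list(rescuer) || !all(RESCUER_PARAMS %in% names(rescuer))) {
    stop_domain(sprintf("rescuer parameters must supply all of: %s",
                        paste(RESCUER_PARAMS, collapse = ", ")))
  }
  unclass(do.call(rescuer_params, rescuer[RESCUER_PARAMS]))
}

as_patient <- function(patient) {
  if (inherits(patient, "patient_params")) return(unclass(patient))
  if (is.numeric(patient) && length(patient) == 1 && is.null(names(patient))) {
    return(unclass(patient_params(patient)))
  }
  if (is.data.frame(patient)) patient <- as.list(patient)
  if (is.list(patient) && !is.null(patient$q_max)) {
    return(unclass(patient_params(patient$q_max)))
  }
  stop_domain("patient must be a `patient_params`, a bare q_max value, or a list with `q_max`")
}

as_constants <- function(constants) {
  if (inherits(constants, "model_constants")) return(unclass(constants))
  if (is.list(constants)) return(unclass(do.call(model_constants, constants)))
  stop_domain("constants must come from model_constants()")
}

check_bounds_tbl <- function(bounds, required = NULL) {
  if (!is.data.frame(bounds) ||
      !all(c("parameter", "lower", "upper") %in% names(bounds))) {
    stop_config("bounds must be a data frame with columns parameter, lower, upper")
  }
  if (any(bounds$lower > bounds$upper)) {
    bad <- bounds$parameter[bounds$lower > bounds$upper]
    stop_config(sprintf("bounds for %s have lower > upper", paste(bad, collapse = ", ")))
  }
  if (!is.null(required) && !all(required %in% bounds$parameter)) {
    stop_config(sprintf("bounds must cover parameters: %s",
                        paste(setdiff(required, bounds$parameter), collapse = ", ")))
  }
  as_tibble(bounds)
}
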