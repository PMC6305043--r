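# Closed-form steady-state gas-exchange model of blood gas delivery during
# CPR. Delivery of each blood gas is D = Q_bar * delta_C: mean blood flow
# times the blood-gas concentration change across the exchange site.
#
# Three formula variants are provided because the closed-form delivery
# expressions and the component equations they were derived from disagree:
#  * "as_printed"    - the published closed forms, verbatim. The CO2
#                      delivery numerator carries the O2 dissociation slope
#                      and the inspired O2 fraction, and the implied average
#                      ventilation rate is R = 1/t.
#  * "corrected_co2" - as_printed with the CO2 numerator symbols swapped to
#                      the CO2 quantities (s_CO2, f_I_CO2).
#  * "explicit_R"    - full composition of the mass-balance pieces with
#                      R = 1/(x*t + T), one ventilation per full
#                      compression-plus-ventilation cycle.

#' Mean blood flow during CPR
#'
#' Compressions drive flow only during the compression fraction of each
#' cycle, giving `Q_bar = q_max * x / (T/t + x)`. Flow is zero with no
#' compressions (`x = 0`), increases monotonically with the ratio `x`, and
#' approaches `q_max` as `x` grows without bound.
#'
#' @param patient Patient parameters ([patient_params()] or bare `q_max`).
#' @param rescuer Rescuer parameters ([rescuer_params()] or a named
#'   list/vector with the six fields).
#' @return Mean blood flow, mL/min.
#' @export
#' @examples
#' mean_blood_flow(patient_params(1000), rescuer_params(x = 30))
mean_blood_flow <- function(patient, rescuer) {
  p <- as_patient(patient)
  r <- as_rescuer(rescuer)
  p$q_max * r$x / (r$T / r$t + r$x)
}

#' Average ventilation rate
#'
#' One ventilation is delivered per full compression-plus-ventilation
#' cycle, so `R = 1 / (x*t + T)` per minute.
#'
#' @inheritParams mean_blood_flow
#' @return Ventilation rate, 1/min.
#' @export
#' @examples
#' ventilation_rate(rescuer_params(x = 30, t = 0.01, T = 0.133))
ventilation_rate <- function(rescuer) {
  r <- as_rescuer(rescuer)
  cycle <- r$x * r$t + r$T
  if (cycle <= 0) stop_domain("cycle time x*t + T must be strictly positive")
  1 / cycle
}

#' Alveolar gas fractions
#'
#' Steady-state alveolar (= end-tidal) fractions from the lung mass
#' balance: effective alveolar ventilation `(v_t - v_d) * R` dilutes or
#' concentrates each gas against blood uptake/release `Q_bar * s`.
#' O2 is taken up, so `f_A_O2 <= f_I_O2`; CO2 is released, so
#' `f_A_CO2 >= f_I_CO2`. When perfusion-driven CO2 release outruns
#' effective ventilation (`(v_t - v_d)*R <= Q_bar*s_CO2`) the steady state
#' has no physical solution and a singularity error is raised.
#'
#' @inheritParams mean_blood_flow
#' @param constants Model constants from [model_constants()].
#' @param Q_bar Mean blood flow, mL/min.
#' @param R Average ventilation rate, 1/min.
#' @return Named list with `f_A_O2` and `f_A_CO2`.
#' @export
alveolar_fractions <- function(rescuer, constants = model_constants(), Q_bar, R) {
  r <- as_rescuer(rescuer)
  k <- as_constants(constants)
  if (r$v_t <= k$v_d) {
    stop_domain(sprintf("tidal volume v_t (%g mL) must exceed dead space v_d (%g mL)",
                        r$v_t, k$v_d))
  }
  if (R <= 0) stop_domain("ventilation rate R must be strictly positive")
  if (Q_bar < 0) stop_domain("mean blood flow Q_bar must be nonnegative")
  va <- (r$v_t - k$v_d) * R
  den_co2 <- va - Q_bar * k$s_CO2
  if (den_co2 <= 0) {
    stop_singularity(sprintf(
      "CO2 balance singular: effective alveolar ventilation %g mL/min does not exceed perfusion term %g mL/min",
      va, Q_bar * k$s_CO2))
  }
  list(f_A_O2 = va * r$f_I_O2 / (va + Q_bar * k$s_O2),
       f_A_CO2 = va * r$f_I_CO2 / den_co2)
}

#' Blood-gas concentration changes
#'
#' Within the linear range of the dissociation curves the concentration
#' change is proportional to the alveolar fraction: `delta_C = s * f_A`.
#'
#' @param f_A_O2,f_A_CO2 Alveolar fractions in `[0, 1]`.
#' @param constants Model constants from [model_constants()].
#' @return Named list with `delta_C_O2` and `delta_C_CO2`, mL gas / mL blood.
#' @export
delta_concentrations <- function(f_A_O2, f_A_CO2, constants = model_constants()) {
  k <- as_constants(constants)
  if (any(c(f_A_O2, f_A_CO2) < 0) || any(c(f_A_O2, f_A_CO2) > 1)) {
    stop_domain("alveolar fractions must lie in [0, 1]")
  }
  list(delta_C_O2 = k$s_O2 * f_A_O2, delta_C_CO2 = k$s_CO2 * f_A_CO2)
}

# Vectorized core. All arguments recycled to a common length; infeasible
# combinations (v_t <= v_d, nonpositive CO2 denominator, nonpositive
# compression time) yield NA outputs with feasible = FALSE rather than an
# error, so grid sweeps and annealing proposals can skip them cheaply.
bgd_compute <- function(q_max, T, t, x, v_t, f_I_O2, f_I_CO2,
                        v_d = 150, s_O2 = 1.5, s_CO2 = 0.8,
                        variant = "as_printed") {
  variant <- match.arg(variant, MODEL_VARIANTS)
  n <- max(lengths(list(q_max, T, t, x, v_t, f_I_O2, f_I_CO2)))
  q_max <- rep_len(q_max, n); T <- rep_len(T, n); t <- rep_len(t, n)
  x <- rep_len(x, n); v_t <- rep_len(v_t, n)
  f_I_O2 <- rep_len(f_I_O2, n); f_I_CO2 <- rep_len(f_I_CO2, n)

  ok <- t > 0 & T >= 0 & x >= 0 & v_t > v_d & q_max > 0 &
    f_I_O2 >= 0 & f_I_O2 <= 1 & f_I_CO2 >= 0 & f_I_CO2 <= 1
  Q_bar <- ifelse(ok, q_max * x / (T / t + x), NA_real_)
  R_cycle <- ifelse(ok & (x * t + T) > 0, 1 / (x * t + T), NA_real_)
  # the closed-form variants substitute one ventilation per compression
  R_eff <- if (variant == "explicit_R") R_cycle else ifelse(ok, 1 / t, NA_real_)

  va <- (v_t - v_d) * R_eff
  den_co2 <- va - Q_bar * s_CO2
  ok <- ok & !is.na(den_co2) & den_co2 > 0
  va <- ifelse(ok, va, NA_real_)
  Q_bar <- ifelse(ok, Q_bar, NA_real_)
  f_A_O2 <- va * f_I_O2 / (va + Q_bar * s_O2)
  f_A_CO2 <- va * f_I_CO2 / (va - Q_bar * s_CO2)
  delta_C_O2 <- s_O2 * f_A_O2
  delta_C_CO2 <- s_CO2 * f_A_CO2

  if (variant == "as_printed") {
    den_base <- (T / t + x) * (v_t - v_d)
    num <- q_max * s_O2 * x * (v_t - v_d) * f_I_O2
    D_O2 <- num / (den_base + t * x * q_max * s_O2)
    D_CO2 <- num / (den_base - t * x * q_max * s_CO2)
  } else if (variant == "corrected_co2") {
    den_base <- (T / t + x) * (v_t - v_d)
    D_O2 <- q_max * s_O2 * x * (v_t - v_d) * f_I_O2 /
      (den_base + t * x * q_max * s_O2)
    D_CO2 <- q_max * s_CO2 * x * (v_t - v_d) * f_I_CO2 /
      (den_base - t * x * q_max * s_CO2)
  } else {
    D_O2 <- Q_bar * delta_C_O2
    D_CO2 <- Q_bar * delta_C_CO2
  }
  D_O2 <- ifelse(ok, D_O2, NA_real_)
  D_CO2 <- ifelse(ok, D_CO2, NA_real_)

  tibble(
    Q_bar = Q_bar,
    R = if (variant == "explicit_R") ifelse(ok, R_cycle, NA_real_) else NA_real_,
    f_A_O2 = ifelse(ok, f_A_O2, NA_real_),
    f_A_CO2 = ifelse(ok, f_A_CO2, NA_real_),
    delta_C_O2 = ifelse(ok, delta_C_O2, NA_real_),
    delta_C_CO2 = ifelse(ok, delta_C_CO2, NA_real_),
    D_O2 = D_O2,
    D_CO2 = D_CO2,
    D_total = D_O2 + D_CO2,
    feasible = ok
  )
}

#' Evaluate the delivery model for one parameter set
#'
#' Computes every intermediate and final model output for a single
#' patient/rescuer configuration: mean blood flow `Q_bar`, alveolar
#' fractions, concentration changes, the two deliveries and their sum
#' `D_total` (mL gas/min). Infeasible inputs raise typed errors: a
#' `cproptim_domain_error` when `v_t <= v_d` or a parameter sign is wrong,
#' a `cproptim_singularity_error` when the CO2 balance has no steady state.
#'
#' @inheritParams mean_blood_flow
#' @param constants Model constants from [model_constants()].
#' @param variant One of `"as_printed"` (default), `"corrected_co2"`,
#'   `"explicit_R"`. See the package vignette for the distinction.
#' @return A one-row tibble (class `delivery_snapshot`) holding the inputs,
#'   the variant, and all model outputs.
#' @export
#' @examples
#' blood_gas_delivery(patient_params(1000), rescuer_params(x = 30))
blood_gas_delivery <- function(patient, rescuer, constants = model_constants(),
                               variant = c("as_printed", "corrected_co2", "explicit_R")) {
  variant <- match.arg(variant)
  p <- as_patient(patient)
  r <- as_rescuer(rescuer)
  k <- as_constants(constants)
  if (r$v_t <= k$v_d) {
    stop_domain(sprintf("tidal volume v_t (%g mL) must exceed dead space v_d (%g mL)",
                        r$v_t, k$v_d))
  }
  out <- bgd_compute(p$q_max, r$T, r$t, r$x, r$v_t, r$f_I_O2, r$f_I_CO2,
                     k$v_d, k$s_O2, k$s_CO2, variant)
  if (!out$feasible) {
    stop_singularity(paste(
      "CO2 balance singular for this parameter set:",
      "perfusion-driven CO2 release exceeds effective alveolar ventilation"))
  }
  snap <- dplyr::bind_cols(
    tibble(q_max = p$q_max, T = r$T, t = r$t, x = r$x, v_t = r$v_t,
           f_I_O2 = r$f_I_O2, f_I_CO2 = r$f_I_CO2, variant = variant),
    dplyr::select(out, -"feasible")
  )
  class(snap) <- c("delivery_snapshot", class(snap))
  snap
}

#' Evaluate the delivery model over a table of parameter sets
#'
#' Data-frame-first, vectorized variant of [blood_gas_delivery()]: takes a
#' data frame with columns `q_max`, `T`, `t`, `x`, `v_t`, `f_I_O2`,
#' `f_I_CO2` and appends the model outputs as columns. Infeasible rows get
#' `NA` outputs and `feasible = FALSE` instead of an error, so the function
#' composes with grid and cohort sweeps.
#'
#' @param params Data frame of parameter sets, one row each.
#' @param constants Model constants from [model_constants()].
#' @param variant Formula variant, as in [blood_gas_delivery()].
#' @return The input as a tibble with output columns appended.
#' @export
#' @examples
#' library(tibble)
#' tibble(q_max = c(900, 1000), T = 0.133, t = 0.01, x = 30,
#'        v_t = 800, f_I_O2 = 0.16, f_I_CO2 = 4e-04) |>
#'   bgd_evaluate()
bgd_evaluate <- function(params, constants = model_constants(),
                         variant = c("as_printed", "corrected_co2", "explicit_R")) {
  variant <- match.arg(variant)
  k <- as_constants(constants)
  need <- c("q_max", RESCUER_PARAMS)
  if (!is.data.frame(params) || !all(need %in% names(params))) {
    stop_domain(sprintf("`params` must be a data frame with columns: %s",
                        paste(need, collapse = ", ")))
  }
  out <- bgd_compute(params$q_max, params$T, params$t, params$x, params$v_t,
                     params$f_I_O2, params$f_I_CO2,
                     k$v_d, k$s_O2, k$s_CO2, variant)
  dplyr::bind_cols(as_tibble(params), out) |>
    mutate(variant = variant, .after = dplyr::last_col())
}

#' Weighted total delivery
#'
#' A differentially weighted sum of the two deliveries,
#' `w_O2 * D_O2 + w_CO2 * D_CO2`; with unit weights this is `D_total`.
#'
#' @param snapshot A `delivery_snapshot` (or any list/data frame with
#'   `D_O2` and `D_CO2`).
#' @param w_O2,w_CO2 Nonnegative weights. Defaults 1.
#' @return Weighted delivery, mL/min.
#' @export
weighted_total_delivery <- function(snapshot, w_O2 = 1, w_CO2 = 1) {
  if (w_O2 < 0 || w_CO2 < 0) stop_domain("delivery weights must be nonnegative")
  if (is.null(snapshot$D_O2) || is.null(snapshot$D_CO2)) {
    stop_domain("snapshot must carry D_O2 and D_CO2")
  }
  w_O2 * snapshot$D_O2 + w_CO2 * snapshot$D_CO2
}

#' Report model-domain violations without raising
#'
#' Checks every precondition [blood_gas_delivery()] enforces and returns a
#' tibble of violations (empty when the evaluation would succeed). Each row
#' names the offending parameter(s), the violated condition, and a message.
#' Unlike the constructors this never raises, so it can triage arbitrary
#' candidate parameter sets.
#'
#' @param patient,rescuer Parameter sets; lenient named lists/vectors are
#'   accepted so that invalid values can be reported rather than rejected.
#' @param constants Model constants from [model_constants()].
#' @param variant Formula variant, as in [blood_gas_delivery()].
#' @param bounds Optional bounds tibble; when given, out-of-bound rescuer
#'   values are reported as `"bound"` violations.
#' @return Tibble with columns `parameter`, `condition`, `message`.
#' @export
#' @examples
#' validate_domain(patient_params(900), rescuer_params())
validate_domain <- function(patient, rescuer, constants = model_constants(),
                            variant = c("as_printed", "corrected_co2", "explicit_R"),
                            bounds = NULL) {
  variant <- match.arg(variant)
  k <- as_constants(constants)
  grab <- function(obj, nm) {
    v <- if (is.data.frame(obj) || is.list(obj)) obj[[nm]] else unname(obj[nm])
    if (is.null(v) || length(v) != 1 || !is.numeric(v) || is.na(v)) NA_real_ else as.numeric(v)
  }
  q_max <- if (is.numeric(patient) && length(patient) == 1 && is.null(names(patient))) {
    as.numeric(patient)
  } else grab(patient, "q_max")
  r <- setNames(lapply(RESCUER_PARAMS, function(nm) grab(rescuer, nm)), RESCUER_PARAMS)

  viol <- list()
  add <- function(parameter, condition, message) {
    viol[[length(viol) + 1]] <<- tibble(parameter = parameter,
                                        condition = condition,
                                        message = message)
  }
  if (is.na(q_max) || q_max <= 0) {
    add("q_max", "positivity", "q_max must be a strictly positive flow in mL/min")
  }
  if (is.na(r$t) || r$t <= 0) add("t", "positivity", "compression time t must be > 0 min")
  if (is.na(r$T) || r$T < 0) add("T", "positivity", "ventilation time T must be >= 0 min")
  if (is.na(r$x) || r$x < 0) add("x", "positivity", "ratio x must be >= 0")
  if (is.na(r$v_t) || r$v_t <= 0) add("v_t", "positivity", "tidal volume v_t must be > 0 mL")
  for (nm in c("f_I_O2", "f_I_CO2")) {
    if (is.na(r[[nm]]) || r[[nm]] < 0 || r[[nm]] > 1) {
      add(nm, "fraction_range", sprintf("%s must lie in [0, 1]", nm))
    }
  }
  if (!is.na(r$v_t) && r$v_t > 0 && r$v_t <= k$v_d) {
    add("v_t", "dead_space", sprintf(
      "tidal volume v_t (%g mL) must exceed dead-space volume v_d (%g mL)", r$v_t, k$v_d))
  }
  if (!is.null(bounds)) {
    b <- check_bounds_tbl(bounds)
    for (i in seq_len(nrow(b))) {
      nm <- b$parameter[i]
      v <- if (nm == "q_max") q_max else r[[nm]]
      if (!is.null(v) && !is.na(v) && (v < b$lower[i] || v > b$upper[i])) {
        add(nm, "bound", sprintf("%s = %g outside [%g, %g]", nm, v, b$lower[i], b$upper[i]))
      }
    }
  }
  if (length(viol) == 0) {
    out <- bgd_compute(q_max, r$T, r$t, r$x, r$v_t, r$f_I_O2, r$f_I_CO2,
                       k$v_d, k$s_O2, k$s_CO2, variant)
    if (!out$feasible) {
      add(c("x, t, v_t, q_max"), "co2_singularity",
          "perfusion-driven CO2 release exceeds effective alveolar ventilation")
    }
  }
  if (length(viol) == 0) {
    tibble(parameter = character(), condition = character(), message = character())
  } else {
    bind_rows(viol)
  }
}
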