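# Shared fixtures. The worked example was hand-evaluated independently
# (spreadsheet/REPL arithmetic on the closed forms) before the model code
# was written; the exact fractions are frozen here.

nominal_rescuer <- function(...) rescuer_params(...)

fixture_inputs <- list(q_max = 1000, T = 0.133, t = 0.01, x = 30,
                       v_t = 800, f_I_O2 = 0.16, f_I_CO2 = 4e-04)

# as_printed closed forms at the fixture point:
#   numerator        = 1000 * 1.5 * 30 * 650 * 0.16 = 4,680,000
#   O2 denominator   = 43.3 * 650 + 0.01*30*1000*1.5 = 28,595
#   CO2 denominator  = 43.3 * 650 - 0.01*30*1000*0.8 = 27,905
fixture_expected <- list(
  Q_bar   = 1000 * 30 / 43.3,
  D_O2    = 4680000 / 28595,
  D_CO2   = 4680000 / 27905,
  D_total = 4680000 / 28595 + 4680000 / 27905,
  D_CO2_corrected = 6240 / 27905
)

fixture_snapshot <- function(variant = "as_printed") {
  blood_gas_delivery(fixture_inputs$q_max,
                     fixture_inputs[RESCUER_PARAMS_TEST],
                     variant = variant)
}

RESCUER_PARAMS_TEST <- c("T", "t", "x", "v_t", "f_I_O2", "f_I_CO2")

# Random interior points of the default box, away from the edges so central
# finite differences stay inside.
interior_points <- function(n, seed = 123, margin = 0.05) {
  b <- default_bounds()
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      v <- b$lower + (margin + (1 - 2 * margin) * runif(nrow(b))) * (b$upper - b$lower)
      setNames(as.list(v), b$parameter)
    })
  })
}

fast_anneal_config <- function(seed = 1L, ...) {
  anneal_config(steps_per_temperature = 40, cooling_factor = 0.85,
                min_temperature = 1e-3, seed = seed, ...)
}

small_sweep_config <- function(q_max_values = c(700, 900), seeds = 1L,
                               schemes = c("global", "sequential")) {
  sweep_config(
    q_max_values = q_max_values, schemes = schemes, seeds = seeds,
    scheme_config = scheme_config(annealing = fast_anneal_config(),
                                  per_cycle_budget = 150, max_cycles = 12))
}
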