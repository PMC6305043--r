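# Bounded continuous simulated annealing with Metropolis acceptance and a
# geometric cooling schedule. The annealer strictly minimizes; callers that
# maximize (the optimization schemes) negate their objective once.

#' Annealing configuration
#'
#' @param initial_temperature Starting temperature, in objective units.
#'   `NULL` (default) auto-calibrates it from 100 seeded probe proposals at
#'   the start point so that the median uphill move is accepted with
#'   probability about 0.8.
#' @param cooling_factor Geometric cooling multiplier in (0, 1); the
#'   temperature is multiplied by this after each sweep.
#' @param steps_per_temperature Proposals per temperature level (>= 1).
#' @param min_temperature Temperature at which the run stops, objective
#'   units (> 0).
#' @param neighbor_scale Base proposal width as a fraction of each
#'   parameter's bound width, in (0, 1].
#' @param max_evaluations Optional cap on total proposals; `NULL` means the
#'   run is limited only by the temperature schedule.
#' @param seed Integer seed; a run is fully deterministic given the seed,
#'   the start state and the objective.
#' @return A list of class `anneal_config`.
#' @export
anneal_config <- function(initial_temperature = NULL, cooling_factor = 0.92,
                          steps_per_temperature = 100, min_temperature = 1e-3,
                          neighbor_scale = 0.15, max_evaluations = NULL,
                          seed = 1L) {
  if (!is.null(initial_temperature) &&
      (!is.numeric(initial_temperature) || initial_temperature <= 0)) {
    stop_config("initial_temperature must be NULL or > 0")
  }
  if (cooling_factor <= 0 || cooling_factor >= 1) {
    stop_config("cooling_factor must lie strictly in (0, 1)")
  }
  if (steps_per_temperature < 1) stop_config("steps_per_temperature must be >= 1")
  if (min_temperature <= 0) stop_config("min_temperature must be > 0")
  if (neighbor_scale <= 0 || neighbor_scale > 1) {
    stop_config("neighbor_scale must lie in (0, 1]")
  }
  if (!is.null(max_evaluations) && max_evaluations < 1) {
    stop_config("max_evaluations must be NULL or >= 1")
  }
  structure(list(initial_temperature = initial_temperature,
                 cooling_factor = cooling_factor,
                 steps_per_temperature = as.integer(steps_per_temperature),
                 min_temperature = min_temperature,
                 neighbor_scale = neighbor_scale,
                 max_evaluations = if (is.null(max_evaluations)) NULL else as.integer(max_evaluations),
                 seed = as.integer(seed)),
            class = "anneal_config")
}

#' Metropolis acceptance probability
#'
#' Downhill moves (`delta_energy <= 0`) are always accepted; uphill moves
#' are accepted with Boltzmann probability `exp(-delta_energy/temperature)`.
#'
#' @param delta_energy Energy change of the proposed move, objective units.
#' @param temperature Current temperature (> 0), objective units.
#' @return Probability in `[0, 1]`. Vectorized over `delta_energy`.
#' @export
#' @examples
#' acceptance_probability(c(-5, 0, 2), temperature = 2)
acceptance_probability <- function(delta_energy, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0) {
    stop_domain("temperature must be a single strictly positive number")
  }
  ifelse(delta_energy <= 0, 1, exp(-delta_energy / temperature))
}

#' Helmholtz free energy over a finite state set
#'
#' Diagnostic linking the annealing temperature to the balance between
#' expected energy and entropy: with Boltzmann occupation probabilities
#' `p_i = exp(-E_i/T) / sum_j exp(-E_j/T)`, returns
#' `sum(p*E) + T * sum(p*log(p))`. At low temperature the minimum energy
#' dominates; at high temperature the entropy term spreads mass evenly.
#' Not used inside the search loop.
#'
#' @param energies Nonempty numeric vector of finite state energies.
#' @param temperature Temperature (> 0), objective units.
#' @return Free energy, objective units.
#' @export
#' @examples
#' free_energy(c(3, 3), temperature = 2)  # 3 - 2*log(2)
free_energy <- function(energies, temperature) {
  if (length(energies) == 0) stop_domain("energies must be a nonempty vector")
  if (!all(is.finite(energies))) stop_domain("energies must all be finite")
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0) {
    stop_domain("temperature must be a single strictly positive number")
  }
  # log-sum-exp for stable Boltzmann weights at low temperature
  z <- -energies / temperature
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  entropy_term <- sum(ifelse(p > 0, p * log(p), 0))
  sum(p * energies) + temperature * entropy_term
}

#' Propose a bounded neighbor state
#'
#' Perturbs each free parameter by a uniform draw of full width
#' `scale * (upper - lower)`, then reflects any excursion back into the
#' box. Reflection (rather than clipping) keeps proposal mass from piling
#' onto corners while still allowing corner optima to be approached.
#' Zero-width coordinates and `scale = 0` leave parameters unchanged.
#' Draws come from the current global RNG stream.
#'
#' @param state Named numeric vector, inside `bounds`.
#' @param bounds Bounds tibble (`parameter`, `lower`, `upper`) covering
#'   every name in `state`.
#' @param scale Proposal width fraction in `[0, 1]`.
#' @return Named numeric vector inside the box.
#' @export
propose_neighbor <- function(state, bounds, scale) {
  b <- check_bounds_tbl(bounds, required = names(state))
  b <- b[match(names(state), b$parameter), ]
  if (any(state < b$lower - 1e-12) || any(state > b$upper + 1e-12)) {
    stop_domain("state must lie inside its bounds")
  }
  width <- b$upper - b$lower
  step <- runif(length(state), -0.5, 0.5) * scale * width
  out <- state + step
  # reflect into the box; one pass suffices since |step| <= width/2
  over <- out > b$upper
  out[over] <- 2 * b$upper[over] - out[over]
  under <- out < b$lower
  out[under] <- 2 * b$lower[under] - out[under]
  pmin(pmax(out, b$lower), b$upper)
}

# Probe the start neighbourhood to set the initial temperature so that the
# median uphill move is accepted with probability ~0.8.
calibrate_temperature <- function(objective, start, bounds, scale, n_probe = 100) {
  e0 <- objective(start)
  deltas <- vapply(seq_len(n_probe), function(i) {
    e <- objective(propose_neighbor(start, bounds, scale))
    if (is.na(e) || !is.finite(e)) NA_real_ else e - e0
  }, numeric(1))
  uphill <- deltas[!is.na(deltas) & deltas > 0]
  if (length(uphill) == 0) return(max(abs(e0) * 0.1, 1))
  max(median(uphill) / (-log(0.8)), 1e-6)
}

#' Simulated annealing over a bounded box
#'
#' Minimizes `objective` over the box given by `bounds`, starting from
#' `start`, with Metropolis acceptance and geometric cooling. The objective
#' must return a finite energy or `NA`/`Inf` to flag an infeasible point;
#' infeasible proposals are always rejected and can never become the best
#' state. Proposal widths shrink with the square root of the relative
#' temperature (floored at 10% of the base width) so early sweeps explore
#' globally and late sweeps refine locally. Runs are deterministic given
#' `config$seed`; the caller's RNG state is left untouched.
#'
#' @param objective Function taking a named numeric vector and returning a
#'   scalar energy (lower is better), or `NA`/`Inf` for infeasible.
#' @param bounds Bounds tibble (`parameter`, `lower`, `upper`) naming the
#'   free parameters.
#' @param config An [anneal_config()].
#' @param start Named numeric vector inside the box; must evaluate to a
#'   finite energy.
#' @return An `annealing_result`: list with `best_state` (named vector),
#'   `best_energy`, `energy_trace` (best-so-far after each proposal),
#'   `temperature_trace` (tibble of per-level temperature, best energy and
#'   best parameters), `acceptance_count`, `proposal_count`,
#'   `final_temperature`.
#' @export
anneal <- function(objective, bounds, config = anneal_config(), start) {
  b <- check_bounds_tbl(bounds)
  if (is.null(names(start)) || !all(names(start) %in% b$parameter)) {
    stop_config("start must be a named vector covered by bounds")
  }
  b <- b[match(names(start), b$parameter), ]
  if (any(start < b$lower) || any(start > b$upper)) {
    stop_config("start must lie inside the bounds box")
  }
  e_start <- objective(start)
  if (is.null(e_start) || is.na(e_start) || !is.finite(e_start)) {
    stop_infeasible("objective is infeasible or non-finite at the start point")
  }

  lower <- b$lower; upper <- b$upper
  width <- upper - lower
  npar <- length(start)
  movable <- which(width > 0)
  # Search move: perturb one coordinate at a time (cycling through a random
  # coordinate each proposal), with the same uniform-draw-and-reflect rule
  # as propose_neighbor(). Single-coordinate moves keep the acceptance rate
  # useful in several dimensions once the temperature is low.
  propose_fast <- function(state, scale) {
    if (length(movable) == 0) return(state)
    j <- if (length(movable) == 1) movable else movable[sample.int(length(movable), 1)]
    out <- state
    out[j] <- state[j] + runif(1, -0.5, 0.5) * scale * width[j]
    if (out[j] > upper[j]) out[j] <- 2 * upper[j] - out[j]
    if (out[j] < lower[j]) out[j] <- 2 * lower[j] - out[j]
    out[j] <- min(max(out[j], lower[j]), upper[j])
    out
  }

  withr::with_seed(config$seed, {
    temp0 <- config$initial_temperature %||%
      calibrate_temperature(objective, start, b, config$neighbor_scale)

    budget <- config$max_evaluations %||% Inf
    n_levels <- max(1L, ceiling(log(config$min_temperature / temp0) /
                                  log(config$cooling_factor)))
    cap <- min(budget, n_levels * config$steps_per_temperature)
    energy_trace <- numeric(cap)

    current <- start; e_current <- e_start
    best <- start; e_best <- e_start
    temp <- temp0
    accepted <- 0L; proposed <- 0L
    level <- 0L
    level_rows <- list()

    while (temp > config$min_temperature && proposed < budget) {
      level <- level + 1L
      scale <- config$neighbor_scale * max(sqrt(temp / temp0), 0.1)
      for (s in seq_len(config$steps_per_temperature)) {
        if (proposed >= budget) break
        cand <- propose_fast(current, scale)
        e_cand <- objective(cand)
        proposed <- proposed + 1L
        feasible <- !is.null(e_cand) && !is.na(e_cand) && is.finite(e_cand)
        if (feasible &&
            runif(1) < acceptance_probability(e_cand - e_current, temp)) {
          current <- cand; e_current <- e_cand
          accepted <- accepted + 1L
          if (e_cand < e_best) { best <- cand; e_best <- e_cand }
        }
        energy_trace[proposed] <- e_best
      }
      level_rows[[level]] <- c(temperature = temp, best_energy = e_best, best)
      temp <- temp * config$cooling_factor
    }
    energy_trace <- energy_trace[seq_len(proposed)]

    temperature_trace <- as_tibble(do.call(rbind, level_rows))
    structure(list(best_state = best,
                   best_energy = e_best,
                   energy_trace = energy_trace,
                   temperature_trace = temperature_trace,
                   acceptance_count = accepted,
                   proposal_count = proposed,
                   final_temperature = temp,
                   initial_temperature = temp0,
                   config = config),
              class = "annealing_result")
  })
}

#' @export
print.annealing_result <- function(x, ...) {
  cat("Simulated annealing result\n")
  cat(sprintf("  best energy: %.6g after %d proposals (%.1f%% accepted)\n",
              x$best_energy, x$proposal_count,
              100 * x$acceptance_count / max(x$proposal_count, 1)))
  cat("  best state:\n")
  print(x$best_state)
  invisible(x)
}

#' Tidy an annealing run into its per-level trace
#'
#' @param x An `annealing_result`.
#' @param ... Unused.
#' @return Tibble with one row per temperature level: `level`,
#'   `temperature`, `best_energy` and the best parameter values.
#' @export
tidy.annealing_result <- function(x, ...) {
  mutate(x$temperature_trace, level = dplyr::row_number(), .before = 1)
}

#' One-row summary of an annealing run
#'
#' @param x An `annealing_result`.
#' @param ... Unused.
#' @return One-row tibble with the best energy, counts and temperatures.
#' @export
glance.annealing_result <- function(x, ...) {
  tibble(best_energy = x$best_energy,
         proposals = x$proposal_count,
         accepted = x$acceptance_count,
         acceptance_rate = x$acceptance_count / max(x$proposal_count, 1),
         initial_temperature = x$initial_temperature,
         final_temperature = x$final_temperature)
}

#' Plot the best-so-far energy of an annealing run
#'
#' @param object An `annealing_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.annealing_result <- function(object, ...) {
  df <- tibble(proposal = seq_along(object$energy_trace),
               best_energy = object$energy_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$proposal, y = .data$best_energy)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "proposal", y = "best-so-far energy",
                  title = "Simulated annealing convergence") +
    ggplot2::theme_minimal()
}
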