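# Simplified parallel simulated-annealing baseline.
#
# Implements the elements that define the algorithm family: Metropolis
# acceptance, Boltzmann mixing of states across chains, an initial burn
# at constant temperature, and the freeze stopping condition.  The
# adaptive Lam temperature schedule and its running statistics estimators
# are deliberately out of scope; a pluggable schedule (default geometric
# cooling) and acceptance-ratio-targeted Gaussian proposals stand in for
# them, and runs with this baseline measure qualitative behaviour only.
# The energy is E(theta) + Pi(theta).

#' Simulated-annealing configuration
#'
#' @param K Number of chains ("processors") mixed together.
#' @param T0 Initial temperature.
#' @param n_init Burn-in iterations at constant `T0` per chain.
#' @param mix_interval Iterations between Boltzmann state mixings (m).
#' @param stat_interval Iterations between log records (tau).
#' @param cooling_rate Geometric cooling factor applied per iteration
#'   after the burn (stand-in schedule; must be in (0, 1]).
#' @param freeze_fraction Relative energy change below which the run is
#'   considered frozen.
#' @param freeze_window Number of consecutive log checks the relative
#'   change must stay below `freeze_fraction`.
#' @param max_iterations Iteration cap.
#' @param proposal_scale Initial Gaussian proposal scale, as a fraction
#'   of each parameter's initial step scale.
#' @return An object of class `sa_config`.
#' @export
sa_config <- function(K = 4, T0 = 100, n_init = 100, mix_interval = 50,
                      stat_interval = 100, cooling_rate = 0.999,
                      freeze_fraction = 1e-4, freeze_window = 5,
                      max_iterations = 10000, proposal_scale = 1) {
  stopifnot(K >= 1, T0 > 0, n_init >= 0, mix_interval >= 1,
            stat_interval >= 1, cooling_rate > 0, cooling_rate <= 1,
            freeze_fraction > 0, freeze_window >= 1, max_iterations >= 1,
            proposal_scale > 0)
  structure(list(K = as.integer(K), T0 = T0, n_init = as.integer(n_init),
                 mix_interval = as.integer(mix_interval),
                 stat_interval = as.integer(stat_interval),
                 cooling_rate = cooling_rate,
                 freeze_fraction = freeze_fraction,
                 freeze_window = as.integer(freeze_window),
                 max_iterations = as.integer(max_iterations),
                 proposal_scale = proposal_scale),
            class = "sa_config")
}

#' One Metropolis move
#'
#' Perturbs one randomly chosen parameter with a Gaussian step. Downhill
#' moves (`dE < 0`) are always accepted; uphill moves are accepted with
#' probability `exp(-dE / T)`. Proposals that violate hard bounds are
#' rejected outright.
#'
#' @param state List with `values` and `energy`.
#' @param energy_fn Function mapping a parameter vector to its energy
#'   (`E + Pi`); may return `Inf`.
#' @param feasible_fn Hard-bound predicate.
#' @param temperature Positive temperature T.
#' @param proposal_sd Per-parameter Gaussian proposal scales.
#' @param stream An [rng_stream()]; `NULL` uses the current RNG.
#' @return The new state, with attribute `accepted`.
#' @export
metropolis_step <- function(state, energy_fn, feasible_fn, temperature,
                            proposal_sd, stream = NULL) {
  stopifnot(temperature > 0)
  run <- function() {
    j <- sample.int(length(state$values), 1L)
    cand <- state$values
    cand[j] <- cand[j] + stats::rnorm(1, 0, proposal_sd[j])
    if (!feasible_fn(cand)) {
      # unacceptable: reject, but keep the draw discipline uniform
      return(list(state = state, accepted = FALSE))
    }
    e_new <- energy_fn(cand)
    dE <- e_new - state$energy
    accept <- is.finite(e_new) &&
      (dE < 0 || stats::runif(1) < exp(-dE / temperature))
    if (accept) list(state = list(values = cand, energy = e_new),
                     accepted = TRUE)
    else list(state = state, accepted = FALSE)
  }
  res <- if (is.null(stream)) run() else with_stream(stream, run())
  out <- res$state
  attr(out, "accepted") <- res$accepted
  out
}

#' Boltzmann mixing of chain states
#'
#' Collects the energies of all chains and reassigns every chain a state
#' drawn independently with probability proportional to
#' `exp(-E_i / T)` (computed stably relative to the minimum energy).
#' This is assignment, not averaging: each new state is one of the
#' current states.
#'
#' @param states List of K states (each with `values`, `energy`).
#' @param temperature Positive temperature.
#' @param stream An [rng_stream()]; `NULL` uses the current RNG.
#' @return List of K states (re-assigned).
#' @export
mix_states <- function(states, temperature, stream = NULL) {
  stopifnot(temperature > 0, length(states) >= 1)
  E <- vapply(states, function(s) s$energy, numeric(1))
  if (all(!is.finite(E))) stop("all chain energies are infinite")
  w <- exp(-(E - min(E[is.finite(E)])) / temperature)
  w[!is.finite(E)] <- 0
  pick <- if (is.null(stream))
    sample.int(length(states), length(states), replace = TRUE, prob = w)
  else with_stream(stream,
    sample.int(length(states), length(states), replace = TRUE, prob = w))
  states[pick]
}

#' Run the simulated-annealing baseline
#'
#' K chains run Metropolis moves over a shared temperature: `n_init`
#' burn-in iterations at constant `T0`, then geometric cooling with
#' Boltzmann mixing every `mix_interval` iterations. Proposal scales
#' adapt towards a 44% acceptance rate between log checks. The run halts
#' when frozen (relative change of the best energy below
#' `freeze_fraction` for `freeze_window` consecutive checks) or at the
#' iteration cap.
#'
#' @param problem Problem list (see [circuit_problem()],
#'   [sphere_problem()]).
#' @param config An [sa_config()].
#' @param seed Base seed; chain `i` uses `seed + i`, mixing uses
#'   `seed + 10007`.
#' @param clock `NULL` for wall time or `function(tick)` (see
#'   [run_ies()]).
#' @return List with `best` (values, energy), `log`, `iterations`,
#'   `frozen`.
#' @export
run_sa <- function(problem, config, seed = 1, clock = NULL) {
  clock_fn <- .make_clock(clock)
  K <- config$K
  streams <- lapply(seq_len(K), function(i) rng_stream(seed + i))
  mix_stream <- rng_stream(seed + 10007L)
  energy_fn <- function(v) {
    E <- problem$objective(v)
    if (!is.finite(E)) return(Inf)
    E + problem$penalty(v)
  }
  states <- lapply(seq_len(K), function(i) {
    v <- drop(problem$sample_init(1, streams[[i]]))
    list(values = v, energy = energy_fn(v))
  })
  scale <- lapply(seq_len(K),
                  function(i) config$proposal_scale * problem$sigma0)
  accepts <- integer(K)
  proposals <- integer(K)
  best <- states[[which.min(vapply(states, `[[`, numeric(1), "energy"))]]
  temperature <- config$T0
  log_rows <- list()
  frozen_count <- 0L
  last_best <- NA_real_
  frozen <- FALSE
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    for (i in seq_len(K)) {
      st <- metropolis_step(states[[i]], energy_fn, problem$feasible,
                            temperature, scale[[i]], streams[[i]])
      proposals[i] <- proposals[i] + 1L
      if (attr(st, "accepted")) accepts[i] <- accepts[i] + 1L
      states[[i]] <- list(values = st$values, energy = st$energy)
      if (st$energy < best$energy) best <- states[[i]]
    }
    if (iter > config$n_init) temperature <- temperature * config$cooling_rate
    if (K > 1 && iter %% config$mix_interval == 0)
      states <- mix_states(states, temperature, mix_stream)
    if (iter %% config$stat_interval == 0) {
      log_rows[[length(log_rows) + 1]] <-
        data.frame(generation = iter, elapsed_seconds = clock_fn(iter),
                   best_objective = best$energy,
                   n_evaluations = iter * K)
      # freeze condition on the relative change of the best energy
      if (!is.na(last_best) && is.finite(best$energy)) {
        rel <- abs(last_best - best$energy) /
          max(abs(best$energy), .Machine$double.eps)
        frozen_count <- if (rel < config$freeze_fraction)
          frozen_count + 1L else 0L
        if (frozen_count >= config$freeze_window && iter > config$n_init) {
          frozen <- TRUE
        }
      }
      last_best <- best$energy
      # acceptance-ratio-targeted proposal adaptation (stand-in for the
      # adaptive move generation of full Lam-schedule annealers)
      for (i in seq_len(K)) {
        if (proposals[i] > 0) {
          rate <- accepts[i] / proposals[i]
          fac <- if (rate > 0.44) 1.2 else 1 / 1.2
          scale[[i]] <- scale[[i]] * fac
        }
        accepts[i] <- 0L
        proposals[i] <- 0L
      }
      if (frozen) break
    }
  }
  list(best = best, log = do.call(rbind, log_rows), iterations = iter,
       frozen = frozen, final_temperature = temperature)
}
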