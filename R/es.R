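# One island's (mu, lambda)-Evolution Strategy: stochastic-ranking
# selection, discrete/intermediate recombination, and non-isotropic
# self-adaptive mutation with exponential step-size smoothing.
#
# A population is a list of parallel arrays: theta (lambda x n), sigma
# (lambda x n, per-parameter mutation step sizes), fitness (objective E),
# penalty (soft penalty Pi) and acceptable (hard-bound flag).  Individuals
# violating hard bounds are kept but ranked worst (infinite caches) so
# that step-size adaptation is not biased by resampling.

#' Evolution Strategy configuration
#'
#' Defaults are the standard settings for the gap-gene reverse-engineering
#' problem: population `lambda = 125`, parents `mu = lambda / 5`,
#' recombination factor `chi = 0.85`, ranking probability `P_f = 0.45`,
#' mutation tuning `phi_star = 1`, smoothing `alpha = 0.2`, migration
#' every `m = 200` generations, logging every `tau = 20`, and a run
#' length of 40000 generations.
#'
#' @param lambda_pop Population size per island.
#' @param mu Number of parents selected per generation.
#' @param chi Recombination factor.
#' @param P_f Probability of comparing by fitness when the upper
#'   individual of a ranking pair is penalty-infeasible.
#' @param phi_star Overall mutation-rate tuning factor.
#' @param alpha Exponential smoothing factor for step sizes.
#' @param migration_interval Generations between migrations.
#' @param log_interval Generations between log records / termination
#'   checks (tau).
#' @param max_generations Default run length.
#' @return An object of class `es_config`.
#' @export
es_config <- function(lambda_pop = 125, mu = lambda_pop / 5, chi = 0.85,
                      P_f = 0.45, phi_star = 1, alpha = 0.2,
                      migration_interval = 200, log_interval = 20,
                      max_generations = 40000) {
  mu <- as.integer(mu)
  lambda_pop <- as.integer(lambda_pop)
  stopifnot(mu > 0, mu < lambda_pop, P_f >= 0, P_f <= 1,
            alpha > 0, alpha <= 1, chi >= 0, chi <= 1, phi_star > 0,
            migration_interval >= 1, log_interval >= 1,
            max_generations >= 1)
  structure(list(lambda_pop = lambda_pop, mu = mu, chi = chi, P_f = P_f,
                 phi_star = phi_star, alpha = alpha,
                 migration_interval = as.integer(migration_interval),
                 log_interval = as.integer(log_interval),
                 max_generations = as.integer(max_generations)),
            class = "es_config")
}

.new_population <- function(theta, sigma) {
  lam <- nrow(theta)
  list(theta = theta, sigma = sigma,
       fitness = rep(NA_real_, lam), penalty = rep(NA_real_, lam),
       acceptable = rep(NA, lam))
}

.pop_size <- function(pop) nrow(pop$theta)

.pop_subset <- function(pop, idx) {
  list(theta = pop$theta[idx, , drop = FALSE],
       sigma = pop$sigma[idx, , drop = FALSE],
       fitness = pop$fitness[idx], penalty = pop$penalty[idx],
       acceptable = pop$acceptable[idx])
}

.pop_bind <- function(a, b) {
  list(theta = rbind(a$theta, b$theta), sigma = rbind(a$sigma, b$sigma),
       fitness = c(a$fitness, b$fitness),
       penalty = c(a$penalty, b$penalty),
       acceptable = c(a$acceptable, b$acceptable))
}

.pop_replace <- function(pop, idx, other, other_idx) {
  pop$theta[idx, ] <- other$theta[other_idx, ]
  pop$sigma[idx, ] <- other$sigma[other_idx, ]
  pop$fitness[idx] <- other$fitness[other_idx]
  pop$penalty[idx] <- other$penalty[other_idx]
  pop$acceptable[idx] <- other$acceptable[other_idx]
  pop
}

# evaluate rows of a population; hard-bound violators get infinite caches
.evaluate_rows <- function(pop, problem, rows = seq_len(.pop_size(pop))) {
  for (i in rows) {
    v <- pop$theta[i, ]
    if (!problem$feasible(v)) {
      pop$fitness[i] <- Inf
      pop$penalty[i] <- Inf
      pop$acceptable[i] <- FALSE
    } else {
      pop$fitness[i] <- problem$objective(v)
      pop$penalty[i] <- problem$penalty(v)
      pop$acceptable[i] <- TRUE
    }
  }
  pop
}

#' Initialise an island population
#'
#' Kinetic parameters are sampled uniformly inside their open hard-bound
#' intervals; regulatory parameters uniformly in a symmetric interval
#' sized so the soft penalty is zero at initialisation. Initial step
#' sizes are 10% of each parameter's sampled range. All individuals are
#' evaluated.
#'
#' @param config An [es_config()].
#' @param problem A problem list as built by [circuit_problem()] (or any
#'   list providing `n`, `sample_init`, `sigma0`, `objective`, `penalty`,
#'   `feasible`).
#' @param stream An [rng_stream()].
#' @return An evaluated population.
#' @export
init_population <- function(config, problem, stream) {
  theta <- problem$sample_init(config$lambda_pop, stream)
  sigma <- matrix(problem$sigma0, config$lambda_pop, problem$n,
                  byrow = TRUE)
  .evaluate_rows(.new_population(theta, sigma), problem)
}

#' Stochastic ranking
#'
#' Bubble-sort-like procedure with `lambda` sweeps over adjacent pairs
#' (early exit when a sweep makes no swap). A pair whose penalties are
#' both `<= 0` is compared by fitness. When the upper individual's
#' penalty is `> 0`, the pair is compared by fitness with probability
#' `P_f` and by penalty otherwise. When only the lower individual is
#' infeasible the pair is compared by penalty (the feasible one stays on
#' top).
#'
#' @param pop An evaluated population.
#' @param P_f Fitness-comparison probability for infeasible-top pairs.
#' @param stream An [rng_stream()]; consumed only for infeasible-top
#'   pairs.
#' @param counts If `TRUE`, attach a `counts` attribute with the number
#'   of fitness- and penalty-based comparisons made for infeasible-top
#'   pairs (used to verify the `P_f` branch empirically).
#' @return Integer permutation of individuals, best first.
#' @export
stochastic_rank <- function(pop, P_f = 0.45, stream = NULL,
                            counts = FALSE) {
  if (anyNA(pop$fitness) || anyNA(pop$penalty))
    stop("population contains unevaluated individuals")
  N <- .pop_size(pop)
  ord <- seq_len(N)
  fit <- pop$fitness
  pen <- pop$penalty
  n_fit <- 0L
  n_pen <- 0L
  run <- function() {
    for (sweep in seq_len(N)) {
      swapped <- FALSE
      for (pos in seq_len(N - 1)) {
        i <- ord[pos]
        j <- ord[pos + 1]
        if (pen[i] <= 0 && pen[j] <= 0) {
          swap <- fit[j] < fit[i]
        } else if (pen[i] > 0) {
          if (stats::runif(1) < P_f) {
            n_fit <<- n_fit + 1L
            swap <- fit[j] < fit[i]
          } else {
            n_pen <<- n_pen + 1L
            swap <- pen[j] < pen[i]
          }
        } else {
          # top feasible, bottom infeasible: penalty comparison, no swap
          swap <- FALSE
        }
        if (swap) {
          ord[pos] <<- j
          ord[pos + 1] <<- i
          swapped <- TRUE
        }
      }
      if (!swapped) break
    }
  }
  if (is.null(stream)) run() else with_stream(stream, run())
  if (counts)
    attr(ord, "counts") <- c(fitness = n_fit, penalty = n_pen)
  ord
}

#' Select the top mu individuals
#'
#' @param pop An evaluated population.
#' @param ranked Permutation from [stochastic_rank()] (best first).
#' @param mu Number of parents.
#' @return Population of the `mu` parents in rank order.
#' @export
select_mu <- function(pop, ranked, mu) {
  stopifnot(mu <= length(ranked))
  .pop_subset(pop, ranked[seq_len(mu)])
}

#' Recombination and copying
#'
#' Produces `lambda` offspring from `mu` ranked parents: `mu`
#' recombinants (offspring positions `1..mu`) followed by `lambda - mu`
#' direct copies (positions `mu+1..lambda`, the ones that will be
#' mutated). Each parent is copied `(lambda - mu) %/% mu` times; when
#' there is a remainder the fittest parents receive one extra copy.
#' Parent `k`'s recombinant combines its own vector with the
#' next-fittest parent's and the fittest parent's:
#' `x' = chi * x_k + (1 - chi) * (x_{k+1} + x_1) / 2`
#' (the worst-ranked parent's "next fittest" wraps to the fittest).
#' Recombinants inherit their primary parent's step sizes.
#'
#' @param parents Population of `mu` parents, ranked best-first.
#' @param config An [es_config()].
#' @return Unevaluated population of `lambda` offspring with attribute
#'   `copy_rows` marking the rows to be mutated.
#' @export
recombine <- function(parents, config) {
  mu <- .pop_size(parents)
  lam <- config$lambda_pop
  chi <- config$chi
  if (mu < 2) stop("recombination requires at least 2 parents")
  n_copies <- lam - mu
  base <- n_copies %/% mu
  extra <- n_copies %% mu
  copy_src <- rep(seq_len(mu), times = base + (seq_len(mu) <= extra))
  nxt <- c(seq_len(mu)[-1], 1L) # wrap the worst parent's partner
  rec_theta <- chi * parents$theta +
    (1 - chi) * 0.5 * (parents$theta[nxt, , drop = FALSE] +
                         matrix(parents$theta[1, ], mu, ncol(parents$theta),
                                byrow = TRUE))
  offspring <- .new_population(
    rbind(rec_theta, parents$theta[copy_src, , drop = FALSE]),
    rbind(parents$sigma, parents$sigma[copy_src, , drop = FALSE]))
  attr(offspring, "copy_rows") <- mu + seq_len(n_copies)
  attr(offspring, "copy_src") <- copy_src
  offspring
}

#' Self-adaptive mutation with step-size smoothing
#'
#' Applied only to the direct copies. Step sizes are perturbed
#' multiplicatively,
#' `sigma'_ij = sigma_ij * exp(tau_g N_i + tau_l N_ij)` with
#' `tau_g = phi_star / sqrt(2 n)` and `tau_l = phi_star / sqrt(2 sqrt(n))`;
#' parameters additively, `theta'_ij = theta_ij + sigma'_ij N2_ij`; and
#' the retained step sizes are exponentially smoothed,
#' `sigma_new = alpha * sigma' + (1 - alpha) * sigma_old`. All normal
#' deviates are drawn fresh.
#'
#' @param offspring Population from [recombine()].
#' @param config An [es_config()].
#' @param stream An [rng_stream()].
#' @param rows Rows to mutate; defaults to the `copy_rows` attribute.
#' @return The population with mutated copies (still unevaluated).
#' @export
mutate <- function(offspring, config, stream,
                   rows = attr(offspring, "copy_rows")) {
  if (length(rows) == 0) return(offspring)
  n <- ncol(offspring$theta)
  nc <- length(rows)
  tau_g <- config$phi_star / sqrt(2 * n)
  tau_l <- config$phi_star / sqrt(2 * sqrt(n))
  draws <- with_stream(stream, list(
    Ni = stats::rnorm(nc),
    Nij = matrix(stats::rnorm(nc * n), nc, n),
    N2 = matrix(stats::rnorm(nc * n), nc, n)))
  sigma_old <- offspring$sigma[rows, , drop = FALSE]
  sigma_p <- sigma_old * exp(tau_g * draws$Ni + tau_l * draws$Nij)
  offspring$theta[rows, ] <- offspring$theta[rows, , drop = FALSE] +
    sigma_p * draws$N2
  offspring$sigma[rows, ] <- config$alpha * sigma_p +
    (1 - config$alpha) * sigma_old
  offspring
}

#' One ES generation
#'
#' Rank, select `mu` parents, recombine to `lambda` offspring, mutate the
#' copies, and evaluate the new population (comma selection: parents do
#' not survive).
#'
#' @param pop Evaluated population (size `lambda` or larger after
#'   asynchronous immigration).
#' @param config An [es_config()].
#' @param problem Problem list (see [init_population()]).
#' @param stream The island's [rng_stream()].
#' @return List with the new `pop` and `stats` (`best_fitness`,
#'   `best_values`, `n_evaluations`).
#' @export
generation_step <- function(pop, config, problem, stream) {
  ord <- stochastic_rank(pop, config$P_f, stream)
  parents <- select_mu(pop, ord, config$mu)
  offspring <- recombine(parents, config)
  offspring <- mutate(offspring, config, stream)
  offspring <- .evaluate_rows(offspring, problem)
  best <- which.min(offspring$fitness)
  list(pop = offspring,
       stats = list(best_fitness = offspring$fitness[best],
                    best_values = offspring$theta[best, ],
                    n_evaluations = .pop_size(offspring)))
}

#' Toy unconstrained problem (for algorithm tests)
#'
#' Sphere objective `sum(theta^2)` with zero penalty and no hard bounds;
#' initial points uniform in `[-5, 5]^n`.
#'
#' @param n Dimension.
#' @return A problem list usable with the ES and SA drivers.
#' @export
sphere_problem <- function(n = 4) {
  list(n = n,
       objective = function(values) sum(values^2),
       penalty = function(values) 0,
       feasible = function(values) TRUE,
       sample_init = function(k, stream = NULL) {
         draw <- function() matrix(stats::runif(k * n, -5, 5), k, n)
         if (is.null(stream)) draw() else with_stream(stream, draw())
       },
       sigma0 = rep(0.5, n),
       data_ss = NA_real_)
}
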