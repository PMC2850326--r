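# Shared test fixtures, built in code.

# decay-only circuit: production and diffusion off
decay_only_params <- function(decay = c(log(2) / 10, 0.1)) {
  G <- length(decay)
  # R is negligible so the interphase rule is also pure decay
  gene_circuit_params(W = matrix(0, G, G), m = rep(0, G), h = rep(0, G),
                      R = rep(1e-9, G), D_base = rep(0, G), decay = decay)
}

# a small evaluated population built directly from fitness/penalty values
fake_population <- function(fitness, penalty = rep(0, length(fitness)),
                            n = 2) {
  lam <- length(fitness)
  list(theta = matrix(seq_len(lam * n), lam, n),
       sigma = matrix(1, lam, n),
       fitness = fitness, penalty = penalty,
       acceptable = is.finite(fitness))
}

# quick ES config for toy runs
quick_config <- function(lambda_pop = 20, mu = 4, generations = 100,
                         m = 50, tau = 10) {
  es_config(lambda_pop = lambda_pop, mu = mu, migration_interval = m,
            log_interval = tau, max_generations = generations)
}

# deterministic "clock" for reproducible logs
tick_clock <- function(tick) as.numeric(tick)

# zero-noise canonical toy dataset + problem, cached per session
toy_problem_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- toy_circuit_2g()
      ds <- simulate_dataset(truth, noise_sd = 0)
      cache <<- list(truth = truth, dataset = ds,
                     problem = circuit_problem(ds, truth$schedule,
                                               truth$space, rtol = 1e-3))
    }
    cache
  }
})
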