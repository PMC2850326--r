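# (mu, lambda)-ES island internals: initialisation, stochastic ranking,
# selection, recombination and self-adaptive mutation.

test_that("population initialisation is seeded, in-bounds and complete", {
  toy <- toy_problem_cached()
  cfg <- quick_config(lambda_pop = 25, mu = 5)
  p1 <- init_population(cfg, toy$problem, rng_stream(11))
  p2 <- init_population(cfg, toy$problem, rng_stream(11))
  expect_identical(p1, p2)
  expect_equal(nrow(p1$theta), 25)
  expect_false(anyNA(p1$fitness))
  for (i in seq_len(25)) {
    expect_true(toy$problem$feasible(p1$theta[i, ]))
    expect_equal(toy$problem$penalty(p1$theta[i, ]), 0)
  }
  expect_true(all(p1$sigma > 0))
})

test_that("stochastic ranking sorts feasible populations by fitness", {
  # spec example: fitnesses (3,1,2), all feasible
  pop <- fake_population(c(3, 1, 2))
  expect_equal(stochastic_rank(pop, 0.45, rng_stream(1)), c(2, 3, 1))
  # oracle: plain comparison sort, many random feasible populations
  stream <- rng_stream(99)
  for (rep in 1:50) {
    fit <- with_stream(stream, stats::runif(sample(3:30, 1)))
    pop <- fake_population(fit)
    expect_equal(stochastic_rank(pop, 0.45, stream), order(fit))
  }
})

test_that("stochastic ranking trades fitness vs penalty via P_f", {
  # P_f = 1: pure fitness ordering regardless of penalties
  pop <- fake_population(c(5, 1, 3), penalty = c(9, 4, 0))
  expect_equal(stochastic_rank(pop, 1, rng_stream(1)), c(2, 3, 1))
  # P_f = 0 with {E=10, P=0} vs {E=5, P=7}: feasible individual first
  # (hand trace: infeasible-top pairs always compared by penalty)
  pop2 <- fake_population(c(10, 5), penalty = c(0, 7))
  expect_equal(stochastic_rank(pop2, 0, rng_stream(1)), c(1, 2))
  pop3 <- fake_population(c(5, 10), penalty = c(7, 0))
  expect_equal(stochastic_rank(pop3, 0, rng_stream(1)), c(2, 1))
  # unevaluated individuals are an error
  pop4 <- fake_population(c(1, NA))
  expect_error(stochastic_rank(pop4, 0.45, rng_stream(1)), "unevaluated")
})

test_that("infeasible-top pairs are fitness-compared at rate P_f", {
  # Monte-Carlo check of the branch probability (scaled-down companion
  # of the acceptance-criterion version)
  stream <- rng_stream(7)
  counts <- c(fitness = 0, penalty = 0)
  for (rep in 1:2000) {
    pop <- fake_population(c(2, 1), penalty = c(3, 1))
    ord <- stochastic_rank(pop, 0.45, stream, counts = TRUE)
    counts <- counts + attr(ord, "counts")
  }
  n <- sum(counts)
  p_hat <- counts[["fitness"]] / n
  se <- sqrt(0.45 * 0.55 / n)
  expect_lt(abs(p_hat - 0.45), 3 * se)
})

test_that("selection takes the top mu in rank order", {
  pop <- fake_population(c(4, 2, 8, 1))
  ord <- stochastic_rank(pop, 0.45, rng_stream(1))
  sel <- select_mu(pop, ord, 2)
  expect_equal(sel$fitness, c(1, 2))
  # mu = lambda returns the whole ranked population
  all_sel <- select_mu(pop, ord, 4)
  expect_equal(all_sel$fitness, sort(pop$fitness))
  # idempotent on an already-selected set
  ord2 <- stochastic_rank(all_sel, 0.45, rng_stream(1))
  expect_equal(select_mu(all_sel, ord2, 4)$fitness, all_sel$fitness)
})

test_that("recombination bookkeeping matches the (mu, lambda) counts", {
  n <- 3
  mu <- 25
  parents <- list(theta = matrix(rnorm(mu * n), mu, n),
                  sigma = matrix(1, mu, n),
                  fitness = seq_len(mu), penalty = rep(0, mu),
                  acceptable = rep(TRUE, mu))
  cfg <- es_config(lambda_pop = 125, mu = 25)
  off <- recombine(parents, cfg)
  expect_equal(nrow(off$theta), 125)
  expect_length(attr(off, "copy_rows"), 100)
  # 4 copies per parent when (lambda - mu) is a multiple of mu
  expect_equal(tabulate(attr(off, "copy_src"), 25), rep(4, 25))
  # lambda = 5, mu = 2: 3 copies, fittest parent copied twice
  parents2 <- list(theta = matrix(rnorm(6), 2, 3),
                   sigma = matrix(1, 2, 3), fitness = 1:2,
                   penalty = c(0, 0), acceptable = c(TRUE, TRUE))
  off2 <- recombine(parents2, es_config(lambda_pop = 5, mu = 2))
  expect_equal(tabulate(attr(off2, "copy_src"), 2), c(2, 1))
  expect_equal(nrow(off2$theta), 5)
  # identical parents: every offspring equals the shared vector
  v <- rnorm(n)
  same <- list(theta = matrix(v, 4, n, byrow = TRUE),
               sigma = matrix(1, 4, n), fitness = rep(1, 4),
               penalty = rep(0, 4), acceptable = rep(TRUE, 4))
  off3 <- recombine(same, es_config(lambda_pop = 8, mu = 4))
  for (i in 1:8) expect_equal(off3$theta[i, ], v)
  expect_error(recombine(list(theta = matrix(1, 1, 3),
                              sigma = matrix(1, 1, 3), fitness = 1,
                              penalty = 0, acceptable = TRUE),
                         es_config(lambda_pop = 5, mu = 1)),
               "at least 2")
})

test_that("mutation follows the lognormal step-size rule with smoothing", {
  cfg <- es_config(lambda_pop = 10, mu = 2, alpha = 0.2)
  n <- 4
  off <- list(theta = matrix(0, 10, n), sigma = matrix(0.5, 10, n),
              fitness = rep(NA_real_, 10), penalty = rep(NA_real_, 10),
              acceptable = rep(NA, 10))
  attr(off, "copy_rows") <- 3:10
  # zero step sizes leave parameters untouched
  off0 <- off
  off0$sigma[] <- 0
  m0 <- mutate(off0, cfg, rng_stream(5))
  expect_equal(m0$theta, off0$theta)
  # recombinant rows (1:2) are never mutated
  m1 <- mutate(off, cfg, rng_stream(5))
  expect_equal(m1$theta[1:2, ], off$theta[1:2, ])
  expect_equal(m1$sigma[1:2, ], off$sigma[1:2, ])
  expect_false(any(m1$theta[3:10, ] == 0))
  # step sizes stay strictly positive through many rounds
  cur <- off
  stream <- rng_stream(6)
  for (g in 1:200) {
    cur <- mutate(cur, cfg, stream)
    expect_true(all(cur$sigma > 0))
  }
})

test_that("mutation displacement variance matches its closed form", {
  # theta' - theta = sigma * exp(tau_g N_i + tau_l N_ij) * N2_ij, so the
  # displacement variance is sigma^2 * exp(2 tau_g^2 + 2 tau_l^2)
  # (independent lognormal moment oracle); with phi* = 1 and large n the
  # inflation factor approaches 1 and the variance approaches sigma^2.
  n <- 2
  lam <- 60000
  sigma0 <- 0.7
  cfg <- es_config(lambda_pop = lam, mu = 2, alpha = 0.2)
  off <- list(theta = matrix(0, lam, n), sigma = matrix(sigma0, lam, n),
              fitness = rep(NA_real_, lam), penalty = rep(NA_real_, lam),
              acceptable = rep(NA, lam))
  attr(off, "copy_rows") <- seq_len(lam)
  m <- mutate(off, cfg, rng_stream(123))
  tau_g <- 1 / sqrt(2 * n)
  tau_l <- 1 / sqrt(2 * sqrt(n))
  expected <- sigma0^2 * exp(2 * tau_g^2 + 2 * tau_l^2)
  disp <- as.vector(m$theta)
  # MC standard error of a variance estimate: var * sqrt(2/(N-1)) is the
  # Gaussian approximation; lognormal mixing inflates it, use kurtosis
  v_hat <- stats::var(disp)
  k <- mean((disp - mean(disp))^4) / v_hat^2
  se <- v_hat * sqrt((k - 1) / length(disp))
  expect_lt(abs(v_hat - expected), 3 * se)
})

test_that("a generation keeps size lambda, is seeded, and descends", {
  prob <- sphere_problem(3)
  cfg <- quick_config(lambda_pop = 20, mu = 4)
  s1 <- rng_stream(3)
  pop <- init_population(cfg, prob, s1)
  res <- generation_step(pop, cfg, prob, s1)
  expect_equal(nrow(res$pop$theta), 20)
  expect_equal(res$stats$n_evaluations, 20)
  # determinism: same stream state, same population
  s2 <- rng_stream(3)
  pop_b <- init_population(cfg, prob, s2)
  res_b <- generation_step(pop_b, cfg, prob, s2)
  expect_identical(res$pop, res_b$pop)
  # the ES beats equal-budget random search on the sphere (median over
  # several seeds)
  es_best <- vapply(1:5, function(s) {
    run_ies(prob, quick_config(generations = 50), "serial", 1,
            seed = s)$best$fitness
  }, numeric(1))
  rs_best <- vapply(1:5, function(s) {
    random_search(prob, 50 * 20 + 20, seed = s)$best$fitness
  }, numeric(1))
  expect_lt(stats::median(es_best), stats::median(rs_best))
})

test_that("hard-bound violators are kept but ranked worst", {
  toy <- toy_problem_cached()
  cfg <- quick_config(lambda_pop = 10, mu = 2)
  stream <- rng_stream(21)
  pop <- init_population(cfg, toy$problem, stream)
  # force one individual far out of bounds and re-evaluate
  pop$theta[4, toy$problem$layout$R] <- 99
  pop <- gcies:::.evaluate_rows(pop, toy$problem, 4)
  expect_identical(pop$fitness[4], Inf)
  expect_false(pop$acceptable[4])
  ord <- stochastic_rank(pop, 0.45, stream)
  expect_equal(ord[10], 4)
})
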