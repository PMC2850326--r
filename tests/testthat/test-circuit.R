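# Circuit model: regulatory input, sigmoid, RHS, division rule,
# integration and full schedule simulation.

test_that("regulatory input is the affine map W g + m bcd + h", {
  p <- gene_circuit_params(W = matrix(c(1, 0, 2, 0), 2, 2),
                           m = c(0.5, 0.5), h = c(-1, -1),
                           R = c(10, 10), D_base = c(0, 0),
                           decay = c(0.1, 0.1))
  # conc = 0, bcd = 0 gives u = h exactly
  expect_equal(regulatory_input(p, c(0, 0), 0), c(-1, -1))
  # hand-computed dot product: row (1,2) . (3,4) + 0.5*2 - 1 = 11
  expect_equal(regulatory_input(p, c(3, 4), 2)[1], 3 + 8 + 1 - 1)
  # fixed thresholds pass through when W = 0, m = 0
  p2 <- gene_circuit_params(W = matrix(0, 2, 2), m = c(0, 0),
                            h = c(-2.5, -2.5), R = c(10, 10),
                            D_base = c(0, 0), decay = c(0.1, 0.1))
  expect_equal(regulatory_input(p2, c(7, 9), 3), c(-2.5, -2.5))
  expect_error(regulatory_input(p, c(1, 2, 3), 0), "length 2")
})

test_that("sigmoid is bounded, increasing, with known values", {
  expect_equal(sigmoid_phi(0), 0.5)
  expect_equal(sigmoid_phi(1), 0.5 * (1 / sqrt(2) + 1))
  u <- seq(-50, 50, length.out = 401)
  v <- sigmoid_phi(u)
  expect_true(all(v > 0 & v < 1))
  expect_true(all(diff(v) > 0))
  expect_lt(1 - sigmoid_phi(1e8), 1e-7)
  expect_lt(sigmoid_phi(-1e8), 1e-7)
  expect_error(sigmoid_phi(Inf), "finite")
  expect_equal(sigmoid_phi(0, form = "logistic"), 0.5)
})

test_that("RHS terms: decay, mitosis production switch-off, Laplacian", {
  # uniform field during mitosis: pure decay regardless of D
  p <- gene_circuit_params(W = matrix(1, 2, 2), m = c(1, 1), h = c(0, 0),
                           R = c(20, 20), D_base = c(0.2, 0.2),
                           decay = c(0.05, 0.08))
  st <- embryo_state(matrix(c(3, 3, 3, 7, 7, 7), 3, 2), 0L, c(1, 1, 1), 0)
  rhs <- circuit_rhs(st, p, "mitosis")
  expect_equal(rhs, cbind(rep(-0.05 * 3, 3), rep(-0.08 * 7, 3)))
  # discrete Laplacian with zero-flux ends: conc (0,1,0) -> (d, -2d, d)
  d <- 0.17
  p2 <- gene_circuit_params(W = matrix(0, 1, 1), m = 0, h = 0, R = 1,
                            D_base = d, decay = 1e-12)
  st2 <- embryo_state(matrix(c(0, 1, 0), 3, 1), 0L, c(0, 0, 0), 0)
  expect_equal(circuit_rhs(st2, p2, "mitosis"), cbind(c(d, -2 * d, d)),
               tolerance = 1e-9)
  # effective diffusion scales as 4^n_div
  st4 <- embryo_state(matrix(c(0, 1, 0), 3, 1), 2L, c(0, 0, 0), 0)
  expect_equal(circuit_rhs(st4, p2, "mitosis"), 16 * cbind(c(d, -2 * d, d)),
               tolerance = 1e-9)
})

test_that("division doubles nuclei, copies concentrations, increments n", {
  st <- embryo_state(matrix(1:6, 1, 6), 0L, 5, 0)
  post <- apply_division(st)
  expect_equal(nrow(post$conc), 2)
  expect_equal(post$conc[1, ], 1:6)
  expect_equal(post$conc[2, ], 1:6)
  expect_equal(post$n_div, 1L)
  # two divisions: 4x nuclei and 4x total mass per gene
  post2 <- apply_division(post)
  expect_equal(nrow(post2$conc), 4)
  expect_equal(colSums(post2$conc), 4 * colSums(st$conc))
  # effective diffusion ratio after one division is exactly 4
  p <- gene_circuit_params(W = matrix(0, 1, 1), m = 0, h = 0, R = 1,
                           D_base = 0.25, decay = 1e-12)
  grad <- function(s) circuit_rhs(s, p, "mitosis")[1, 1]
  s0 <- embryo_state(matrix(c(0, 1), 2, 1), 0L, c(0, 0), 0)
  s1 <- embryo_state(matrix(c(0, 1), 2, 1), 1L, c(0, 0), 0)
  expect_equal(grad(s1) / grad(s0), 4)
})

test_that("integration matches closed forms and improves with tolerance", {
  p <- decay_only_params(c(0.06, 0.11))
  st <- embryo_state(matrix(c(5, 3, 2, 8), 2, 2), 0L, c(0, 0), 0)
  # rhs == 0: state unchanged
  p0 <- gene_circuit_params(W = matrix(0, 2, 2), m = c(0, 0), h = c(0, 0),
                            R = c(1, 1), D_base = c(0, 0),
                            decay = c(1e-14, 1e-14))
  out0 <- integrate_interval(st, p0, "mitosis", 0, 25, rtol = 1e-6)
  expect_equal(out0$conc, st$conc, tolerance = 1e-9)
  # exponential decay oracle
  closed <- st$conc * exp(-12 * matrix(c(0.06, 0.11), 2, 2, byrow = TRUE))
  out <- integrate_interval(st, p, "mitosis", 0, 12, rtol = 1e-3)
  expect_equal(out$conc, closed, tolerance = 1e-3)
  # halving the tolerance never increases the error
  errs <- vapply(c(1e-2, 5e-3, 2.5e-3, 1e-4, 1e-6), function(tol) {
    o <- integrate_interval(st, p, "mitosis", 0, 12, rtol = tol)
    max(abs(o$conc - closed))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_error(integrate_interval(st, p, "mitosis", 5, 5), "exceed")
})

test_that("integration agrees with an independent stiff solver", {
  skip_if_not_installed("deSolve")
  # full dynamics: production + diffusion + decay on 3 nuclei, 2 genes
  p <- gene_circuit_params(W = matrix(c(0.01, -0.03, -0.02, 0.015), 2, 2,
                                      byrow = TRUE),
                           m = c(0.05, 0.02), h = c(-2.5, -2.5),
                           R = c(18, 24), D_base = c(0.12, 0.06),
                           decay = c(0.08, 0.05))
  bcd <- c(100, 60, 30)
  st <- embryo_state(matrix(c(10, 5, 1, 0, 2, 4), 3, 2), 0L, bcd, 0)
  ode_rhs <- function(t, y, parms) {
    s <- embryo_state(matrix(pmax(y, 0), 3, 2), 0L, bcd, t)
    list(as.vector(circuit_rhs(s, p, "interphase")))
  }
  ref <- deSolve::ode(as.vector(st$conc), c(0, 15), ode_rhs, NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-9)
  out <- integrate_interval(st, p, "interphase", 0, 15, rtol = 1e-6)
  expect_equal(as.vector(out$conc), as.numeric(ref[2, -1]),
               tolerance = 1e-5)
})

test_that("diffusion conserves mass and concentrations stay non-negative", {
  p <- gene_circuit_params(W = matrix(0, 1, 1), m = 0, h = 0, R = 1e-9,
                           D_base = 0.3, decay = 1e-14)
  st <- embryo_state(matrix(c(9, 0, 0, 3), 4, 1), 0L, rep(0, 4), 0)
  out <- integrate_interval(st, p, "interphase", 0, 30, rtol = 1e-8)
  expect_equal(sum(out$conc), sum(st$conc), tolerance = 1e-6)
  expect_true(all(out$conc >= 0))
})

test_that("simulation follows the mitotic schedule", {
  sched <- toy_schedule()
  G <- 2
  lam <- log(2) / 10 # 10-minute half-life
  p <- decay_only_params(rep(lam, G))
  init <- embryo_state(matrix(c(8, 4, 2, 6, 3, 1), 3, G), 0L,
                       c(0, 0, 0), 0)
  bcd <- list(rep(0, 3), rep(0, 6))
  traj <- simulate_circuit(p, init, sched, c(0, 10, 20, 21, 40), bcd,
                           rtol = 1e-8)
  # decay-only: concentration halves every 10 minutes
  expect_equal(traj$states[[2]]$conc, init$conc / 2, tolerance = 1e-6)
  expect_equal(traj$states[[3]]$conc, init$conc / 4, tolerance = 1e-6)
  # output at the division instant returns the post-division state
  expect_equal(nrow(traj$states[[4]]$conc), 6)
  expect_equal(traj$states[[4]]$n_div, 1L)
  # daughters copy the mother
  expect_equal(traj$states[[4]]$conc[1, ], traj$states[[4]]$conc[2, ])
  # nucleus count stays doubled afterwards
  expect_equal(nrow(traj$states[[5]]$conc), 6)
  # half-life also holds across the division (mass per nucleus halves
  # every 10 min regardless of the split)
  expect_equal(traj$states[[5]]$conc[1, ], init$conc[1, ] / 2^4,
               tolerance = 1e-5)
  # no-division schedule needs no extra Bcd profiles
  sched2 <- mitotic_schedule("interphase", 0, 40)
  traj2 <- simulate_circuit(p, init, sched2, c(10, 30), rtol = 1e-8)
  expect_equal(traj2$states[[1]]$conc, init$conc / 2, tolerance = 1e-6)
  # determinism: bit-identical repeat
  traj3 <- simulate_circuit(p, init, sched, c(0, 10, 20, 21, 40), bcd,
                            rtol = 1e-8)
  expect_identical(traj$states[[5]]$conc, traj3$states[[5]]$conc)
})

test_that("schedule and state validation reject malformed inputs", {
  expect_error(mitotic_schedule("division", 0, 5), "zero duration")
  expect_error(mitotic_schedule(c("interphase", "interphase"),
                                c(0, 10), c(5, 15)), "contiguous")
  expect_error(embryo_state(matrix(-1, 1, 1)), "non-negative")
  expect_error(embryo_state(matrix(1, 2, 1), bcd = c(1, 2, 3)),
               "per nucleus")
})

test_that("trajectory export writes a valid TSV with A-P positions", {
  p <- decay_only_params(c(0.05, 0.05))
  init <- embryo_state(matrix(1:8, 4, 2), 0L, rep(0, 4), 0)
  sched <- mitotic_schedule("interphase", 0, 20)
  traj <- simulate_circuit(p, init, sched, c(0, 20))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_trajectory(traj, path, meta = c(seed = "1"))
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "#"))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(names(df), c("time", "nucleus_index",
                            "ap_position_percent", "gene1", "gene2"))
  expect_equal(nrow(df), 8)
  expect_equal(df$ap_position_percent[1:4], ap_positions(4))
})
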