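# Objective, penalty, hard bounds and parameter packing.

test_that("packed vector length matches N_g(N_g+5), or N_g(N_g+4) fixed h", {
  genes6 <- c("cad", "hb", "Kr", "kni", "gt", "tll")
  p <- gene_circuit_params(W = matrix(0.001, 6, 6), m = rep(0.01, 6),
                           h = rep(-2.5, 6), R = rep(20, 6),
                           D_base = rep(0.1, 6),
                           decay = rep(log(2) / 10, 6), genes = genes6)
  free <- pack_parameters(p, search_space(h_fixed = NULL))
  expect_length(free$values, 66)
  # pinning the four trunk gap-gene thresholds at -2.5 leaves 62
  h_pattern <- c(NA, -2.5, -2.5, -2.5, -2.5, NA)
  part <- pack_parameters(p, search_space(h_fixed = h_pattern))
  expect_length(part$values, 62)
  # fixing every threshold gives N_g * (N_g + 4)
  fixed <- pack_parameters(p, search_space(h_fixed = -2.5))
  expect_length(fixed$values, 60)
  expect_length(parameter_names(free), 66)
  # partial round trip preserves the pinned and free entries
  p$h <- c(-1, -2.5, -2.5, -2.5, -2.5, -3)
  q <- unpack_parameters(pack_parameters(
    p, search_space(h_fixed = h_pattern)))
  expect_equal(q$h, p$h)
})

test_that("pack/unpack is a field-by-field round trip", {
  set.seed(42)
  p <- gene_circuit_params(W = matrix(rnorm(9, 0, 0.01), 3, 3),
                           m = rnorm(3, 0, 0.01), h = rnorm(3),
                           R = runif(3, 10, 30), D_base = runif(3, 0, 0.3),
                           decay = log(2) / runif(3, 5, 20))
  for (space in list(search_space(h_fixed = NULL), search_space())) {
    q <- unpack_parameters(pack_parameters(p, space))
    expect_equal(q$W, p$W)
    expect_equal(q$m, p$m)
    expect_equal(q$R, p$R)
    expect_equal(q$D_base, p$D_base)
    expect_equal(q$decay, p$decay)
    if (is.null(space$h_fixed)) expect_equal(q$h, p$h)
    else expect_equal(q$h, rep(-2.5, 3))
  }
})

test_that("hard bounds are strict and violations are named", {
  space <- search_space()
  p <- gene_circuit_params(W = matrix(0, 2, 2), m = c(0, 0), h = c(0, 0),
                           R = c(20, 20), D_base = c(0.1, 0.1),
                           decay = log(2) / c(10, 10))
  ok <- check_hard_bounds(pack_parameters(p, space), space)
  expect_true(ok$acceptable)
  expect_equal(nrow(ok$violations), 0)
  # out-of-range production rate is rejected with parameter and gene
  p$R[1] <- 35
  bad <- check_hard_bounds(pack_parameters(p, space), space)
  expect_false(bad$acceptable)
  expect_equal(bad$violations$param, "R")
  expect_equal(bad$violations$gene, "gene1")
  # boundary values violate the strict inequalities
  p$R[1] <- 30
  expect_false(check_hard_bounds(pack_parameters(p, space),
                                 space)$acceptable)
  p$R[1] <- 20
  p$decay[2] <- log(2) / 5 # half-life exactly 5 min
  expect_false(check_hard_bounds(pack_parameters(p, space),
                                 space)$acceptable)
})

test_that("penalty is zero inside the band and scales monotonically", {
  space <- search_space()
  gm <- c(200, 150)
  bmax <- 120
  zero <- gene_circuit_params(W = matrix(0, 2, 2), m = c(0, 0),
                              h = c(0, 0), R = c(20, 20),
                              D_base = c(0.1, 0.1),
                              decay = log(2) / c(10, 10))
  th0 <- pack_parameters(zero, search_space(h_fixed = NULL))
  expect_equal(penalty_regulatory(th0, gm, bmax), 0)
  # any parameters satisfying the band bound give exactly zero
  base <- gene_circuit_params(W = matrix(c(0.01, -0.02, -0.015, 0.01),
                                         2, 2), m = c(0.05, 0.02),
                              h = c(-2.5, -2.5), R = c(20, 20),
                              D_base = c(0.1, 0.1),
                              decay = log(2) / c(10, 10))
  u_cap <- drop(abs(base$W) %*% gm) + abs(base$m) * bmax + abs(base$h)
  expect_true(all(u_cap < 1 / sqrt(space$Lambda)))
  expect_equal(penalty_regulatory(pack_parameters(base, space), gm, bmax),
               0)
  # scan a scaling grid: direct evaluation oracle vs implementation
  cs <- seq(1, 40, length.out = 60)
  pis <- vapply(cs, function(cc) {
    p <- base
    p$W <- cc * base$W
    penalty_regulatory(pack_parameters(p, space), gm, bmax)
  }, numeric(1))
  oracle <- vapply(cs, function(cc) {
    uc <- drop(abs(cc * base$W) %*% gm) + abs(base$m) * bmax + 2.5
    sum(pmax(0, space$Lambda * uc^2 - 1))
  }, numeric(1))
  expect_equal(pis, oracle)
  expect_true(all(diff(pis) >= 0))
  expect_true(pis[length(pis)] > 0)
  # penalty never depends on kinetic parameters
  p2 <- base
  p2$R <- c(29, 11)
  p2$D_base <- c(0.29, 0.01)
  p2$decay <- log(2) / c(6, 19)
  expect_equal(penalty_regulatory(pack_parameters(p2, space), gm, bmax),
               penalty_regulatory(pack_parameters(base, space), gm, bmax))
})

test_that("objective is the plain sum of squared residuals", {
  toy <- toy_problem_cached()
  truth <- toy$truth
  ds <- toy$dataset
  th <- pack_parameters(truth$params, truth$space)
  # perfect fit: zero to solver tolerance (relative to the data scale)
  E0 <- objective_E(th, ds, truth$schedule, truth$space, rtol = 1e-8)
  expect_lt(E0 / toy$problem$data_ss, 1e-10)
  # shifting observed values by known residuals adds their squares:
  # residuals (1,2,2) on three observed cells give E = 9
  ds2 <- ds
  idx <- which(ds2$obs$time_class == 30)[1:3]
  ds2$obs$conc[idx] <- ds2$obs$conc[idx] + c(1, 2, 2)
  E1 <- objective_E(th, ds2, truth$schedule, truth$space, rtol = 1e-8)
  expect_equal(E1, 9, tolerance = 2e-3)
  # doubling every residual quadruples E
  ds3 <- ds
  ds3$obs$conc[idx] <- ds3$obs$conc[idx] + c(2, 4, 4)
  E2 <- objective_E(th, ds3, truth$schedule, truth$space, rtol = 1e-8)
  expect_equal(E2, 36, tolerance = 2e-3)
})

test_that("solver failure yields an infinite objective, not an abort", {
  toy <- toy_problem_cached()
  bad <- toy$problem$sample_init(1)[1, ]
  bad[toy$problem$layout$decay] <- 1e9 # absurd stiffness: blow up
  bad[toy$problem$layout$R] <- 1e8
  expect_true(is.finite(toy$problem$objective(
    toy$problem$sample_init(1)[1, ])))
  expect_no_error(E <- toy$problem$objective(bad))
  expect_identical(E, Inf)
})

test_that("expression tables round-trip through TSV", {
  toy <- toy_problem_cached()
  ds <- toy$dataset
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_expression_table(ds, path, meta = c(seed = "1"))
  back <- read_expression_table(path)
  expect_equal(back$genes, ds$genes)
  expect_equal(back$gene_maxima, ds$gene_maxima)
  expect_equal(back$bcd_profiles[["0"]], ds$bcd_profiles[["0"]])
  expect_equal(back$bcd_profiles[["1"]], ds$bcd_profiles[["1"]])
  o1 <- ds$obs[order(ds$obs$time_class, ds$obs$gene,
                     ds$obs$nucleus_index), ]
  o2 <- back$obs[order(back$obs$time_class, back$obs$gene,
                       back$obs$nucleus_index), ]
  expect_equal(o2$conc, o1$conc)
  expect_equal(back$initial$conc, ds$initial$conc)
})

test_that("table reader validates content and reports line numbers", {
  # hand-built 3-row table: gene_maxima equal the column maxima
  lines <- c("time_class\tnucleus_index\tap_position_percent\tbcd\tga\tgb",
             "0\t1\t35\t100\t1\t6",
             "0\t2\t60\t50\t5\t4",
             "10\t1\t35\t100\t3\t9",
             "10\t2\t60\t50\t2\t8")
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  writeLines(lines, path)
  ds <- read_expression_table(path)
  expect_equal(unname(ds$gene_maxima), c(5, 9))
  # negative concentration rejected with its line number
  writeLines(c(lines[1:3], "10\t1\t35\t100\t-3\t9", lines[5]), path)
  expect_error(read_expression_table(path), "line 4")
  # duplicate (time_class, gene, nucleus) key rejected
  obs <- data.frame(time_class = c(0, 0), nucleus_index = c(1, 1),
                    gene = c("ga", "ga"), conc = c(1, 2))
  expect_error(expression_dataset(obs, list("0" = 10), "ga"),
               "duplicate")
})
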