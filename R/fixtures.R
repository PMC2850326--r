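# Synthetic ground-truth circuits and FlyEx-like noisy data sets, so that
# every optimiser and metric is testable without any external data, and
# parameter-recovery experiments with known truth.

#' Default two-cycle mitotic schedule (minutes)
#'
#' Interphase 0-16, mitosis 16-21, an instantaneous division at 21, then
#' interphase 21-40. Small enough for minute-scale optimiser runs while
#' still exercising every model rule (production switch-off, division,
#' diffusion-rate doubling).
#'
#' @export
toy_schedule <- function() {
  mitotic_schedule(kind = c("interphase", "mitosis", "division",
                            "interphase"),
                   start = c(0, 16, 21, 21),
                   end = c(16, 21, 21, 40))
}

# exponential Bcd gradient over the modelled A-P window
.bcd_gradient <- function(n_nuc, ap_range = c(35, 92), B0 = 120,
                          length_scale = 20) {
  ap <- ap_positions(n_nuc, ap_range)
  B0 * exp(-(ap - ap_range[1]) / length_scale)
}

#' Canonical 2-gene mutual-repression toy circuit
#'
#' Fixed parameters: weak auto-activation, mutual repression, Bcd
#' activating gene 1 more strongly than gene 2, thresholds fixed at
#' -2.5. Passes all hard bounds and has zero soft penalty against its
#' own simulated data.
#'
#' @param N_nuc Number of nuclei before the division (default 4).
#' @return A `ground_truth` list: `params`, `schedule`, `bcd_profiles`,
#'   `time_classes`, `initial_state`, `space`.
#' @export
toy_circuit_2g <- function(N_nuc = 4) {
  params <- gene_circuit_params(
    W = matrix(c(0.008, -0.030,
                 -0.025, 0.010), 2, 2, byrow = TRUE),
    m = c(0.050, 0.018),
    h = c(-2.5, -2.5),
    R = c(18, 24),
    D_base = c(0.12, 0.06),
    decay = log(2) / c(9, 14),
    genes = c("geneA", "geneB"))
  .ground_truth(params, N_nuc)
}

.ground_truth <- function(params, N_nuc, seed = NULL) {
  schedule <- toy_schedule()
  bcd_profiles <- list("0" = .bcd_gradient(N_nuc),
                       "1" = .bcd_gradient(2 * N_nuc))
  initial <- embryo_state(matrix(0, N_nuc, n_genes(params)), 0L,
                          bcd_profiles[["0"]], 0)
  structure(list(params = params, schedule = schedule,
                 bcd_profiles = bcd_profiles,
                 time_classes = c(0, 10, 30, 40),
                 initial_state = initial,
                 space = search_space(),
                 seed = seed),
            class = "ground_truth")
}

#' Random ground-truth circuit
#'
#' Kinetic parameters are drawn uniformly inside the open hard-bound
#' intervals; regulatory weights follow a mutual-repression motif
#' (positive self-weights, negative cross-weights) with magnitudes small
#' enough that the soft penalty is zero at the worst-case regulatory
#' input. Thresholds are fixed at -2.5.
#'
#' @param N_g Number of genes (>= 1).
#' @param N_nuc Number of nuclei before the division (>= 1).
#' @param seed RNG seed; the circuit is a pure function of it.
#' @return A `ground_truth` list (see [toy_circuit_2g()]).
#' @export
make_toy_circuit <- function(N_g = 2, N_nuc = 4, seed = 1) {
  stopifnot(N_g >= 1, N_nuc >= 1)
  stream <- rng_stream(seed)
  space <- search_space()
  # worst-case concentration scale: R_max / lambda_min
  conc_cap <- space$R_range[2] * space$halflife_range[2] / log(2)
  bcd_cap <- max(.bcd_gradient(2 * N_nuc))
  # keep sum_b |W| conc_cap + |m| bcd_cap + |h| inside the penalty-free
  # band 1/sqrt(Lambda) with a wide margin
  w_cap <- 0.5 * (1 / sqrt(space$Lambda) - 2.5) / (N_g * conc_cap + bcd_cap)
  params <- with_stream(stream, {
    W <- matrix(-stats::runif(N_g * N_g, 0.3 * w_cap, w_cap), N_g, N_g)
    diag(W) <- stats::runif(N_g, 0, 0.5 * w_cap)
    gene_circuit_params(
      W = W,
      m = stats::runif(N_g, 5, 10) * w_cap,
      h = rep(-2.5, N_g),
      R = stats::runif(N_g, space$R_range[1], space$R_range[2]),
      D_base = stats::runif(N_g, space$D_range[1], space$D_range[2]),
      decay = log(2) / stats::runif(N_g, space$halflife_range[1],
                                    space$halflife_range[2]))
  })
  .ground_truth(params, N_nuc, seed)
}

#' Simulate a noisy expression data set from a ground truth
#'
#' Simulates the circuit over its mitotic schedule, samples all nuclei
#' and genes at the requested time classes, and adds independent
#' Gaussian noise clipped at zero. The earliest time class is the
#' initial condition and is left noise-free, so that with zero noise the
#' truth parameters score an objective of (numerically) zero.
#'
#' @param truth A `ground_truth` (from [toy_circuit_2g()] or
#'   [make_toy_circuit()]).
#' @param time_classes Observation times; default the truth's.
#' @param noise_sd Noise standard deviation in concentration units.
#' @param seed RNG seed for the noise.
#' @param rtol Solver tolerance used for the forward simulation.
#' @return An [expression_dataset()].
#' @export
simulate_dataset <- function(truth, time_classes = truth$time_classes,
                             noise_sd = 0, seed = 1, rtol = 1e-6) {
  traj <- simulate_circuit(truth$params, truth$initial_state,
                           truth$schedule, time_classes,
                           truth$bcd_profiles, rtol = rtol)
  stream <- rng_stream(seed)
  genes <- truth$params$genes
  obs <- do.call(rbind, lapply(seq_along(time_classes), function(k) {
    st <- traj$states[[k]]
    conc <- st$conc
    if (k > 1 && noise_sd > 0) {
      noise <- with_stream(stream,
        matrix(stats::rnorm(length(conc), 0, noise_sd), nrow(conc)))
      conc <- pmax(conc + noise, 0)
    }
    data.frame(time_class = time_classes[k],
               nucleus_index = rep(seq_len(nrow(conc)), ncol(conc)),
               gene = rep(genes, each = nrow(conc)),
               conc = as.vector(conc), stringsAsFactors = FALSE)
  }))
  expression_dataset(obs, truth$bcd_profiles, genes,
                     truth$initial_state$n_div)
}

#' Write ground-truth parameters as a two-column TSV
#'
#' @param truth A `ground_truth`.
#' @param path Output path.
#' @param meta Optional `#` header lines.
#' @export
write_ground_truth <- function(truth, path, meta = NULL) {
  theta <- pack_parameters(truth$params, truth$space)
  nm <- parameter_names(theta)
  .write_tsv(data.frame(name = nm, value = theta$values), path, meta)
}

#' Names of the entries of a packed parameter vector
#'
#' @param theta A `parameter_vector`.
#' @return Character vector, e.g. `"W[geneA<-geneB]"`, `"R[geneA]"`.
#' @export
parameter_names <- function(theta) {
  layout <- theta$layout
  G <- attr(layout, "G")
  g <- theta$genes
  nm <- character(attr(layout, "n"))
  nm[layout$W] <- as.vector(t(outer(g, g, function(a, b)
    paste0("W[", a, "<-", b, "]"))))
  nm[layout$m] <- paste0("m[", g, "]")
  if (!is.null(layout$h)) nm[layout$h] <- paste0("h[", g, "]")
  nm[layout$R] <- paste0("R[", g, "]")
  nm[layout$D_base] <- paste0("D[", g, "]")
  nm[layout$decay] <- paste0("decay[", g, "]")
  nm
}

#' Pure random search (baseline for recovery experiments)
#'
#' Samples candidate parameter vectors from the problem's initial
#' sampler and tracks the best objective, with the same evaluation
#' budget accounting as the ES.
#'
#' @param problem Problem list.
#' @param n_evaluations Total evaluation budget.
#' @param seed RNG seed.
#' @param batch Batch size for sampling.
#' @return List with `best` (values, fitness) and `n_evaluations`.
#' @export
random_search <- function(problem, n_evaluations, seed = 1, batch = 100) {
  stream <- rng_stream(seed)
  best_fit <- Inf
  best_values <- NULL
  done <- 0
  while (done < n_evaluations) {
    k <- min(batch, n_evaluations - done)
    theta <- problem$sample_init(k, stream)
    for (i in seq_len(k)) {
      f <- problem$objective(theta[i, ])
      if (f < best_fit) {
        best_fit <- f
        best_values <- theta[i, ]
      }
    }
    done <- done + k
  }
  list(best = list(values = best_values, fitness = best_fit),
       n_evaluations = n_evaluations)
}

#' Parameter-recovery experiment
#'
#' Runs the island ES `n_runs` times on a data set simulated from a known
#' ground truth and reports, per run: the final objective, whether it
#' fell below `threshold_factor` times the data sum of squares, and the
#' sign agreement between the recovered and true regulatory weights for
#' entries of true magnitude above `w_floor`. A pure random search with
#' the same evaluation budget is run alongside as a baseline.
#'
#' @param truth A `ground_truth`.
#' @param dataset Data set to fit; defaults to a zero-noise simulation
#'   of `truth`.
#' @param config An [es_config()] (its `max_generations` sets the
#'   budget).
#' @param n_runs Number of independent ES runs.
#' @param seed Base seed; run `r` uses `seed + 1000 * r`.
#' @param n_islands Islands per run.
#' @param threshold_factor Success threshold as a fraction of the data
#'   sum of squares.
#' @param w_floor Magnitude floor for the sign-agreement score.
#' @param rtol Solver tolerance for the fitted model.
#' @param random_baseline Whether to run the equal-budget random search.
#'
#' @details Each ES run halts as soon as its best objective has dropped
#' below the success threshold (threshold-hold termination with the run
#' cap as safety), mirroring time-to-target benchmarking; the random
#' search baseline is then given exactly the number of evaluations the
#' ES run consumed.
#' @return List of class `recovery_report`: per-run data frame `runs`,
#'   `success_rate`, `es_median_E`, `rs_median_E`, `data_ss`.
#' @export
recovery_experiment <- function(truth, dataset = NULL,
                                config = es_config(lambda_pop = 20,
                                                   mu = 4,
                                                   migration_interval = 100,
                                                   log_interval = 100,
                                                   max_generations = 8000),
                                n_runs = 10, seed = 1, n_islands = 4,
                                threshold_factor = 1e-3, w_floor = 0.005,
                                rtol = 1e-3, random_baseline = TRUE) {
  if (is.null(dataset))
    dataset <- simulate_dataset(truth, noise_sd = 0, seed = seed)
  problem <- circuit_problem(dataset, truth$schedule, truth$space, rtol)
  truth_theta <- pack_parameters(truth$params, truth$space)
  W_idx <- problem$layout$W
  strong <- abs(truth_theta$values[W_idx]) > w_floor
  threshold <- threshold_factor * problem$data_ss
  stop_at <- termination_spec("threshold_hold",
                              max_generations = config$max_generations,
                              threshold = threshold, hold = 1)
  rows <- lapply(seq_len(n_runs), function(r) {
    run_seed <- seed + 1000L * r
    res <- run_ies(problem, config, "serial", n_islands, seed = run_seed,
                   termination = stop_at)
    w_sign <- if (any(strong)) {
      mean(sign(res$best$values[W_idx][strong]) ==
             sign(truth_theta$values[W_idx][strong]))
    } else NA_real_
    rs_E <- if (random_baseline) {
      rs <- random_search(problem, res$n_evaluations, seed = run_seed + 1L)
      rs$best$fitness
    } else NA_real_
    data.frame(run = r, seed = run_seed, final_E = res$best$fitness,
               generations = res$generations,
               n_evaluations = res$n_evaluations,
               reached = res$best$fitness < threshold,
               w_sign_agreement = w_sign, random_search_E = rs_E)
  })
  runs <- do.call(rbind, rows)
  structure(list(runs = runs,
                 success_rate = mean(runs$reached),
                 es_median_E = stats::median(runs$final_E),
                 rs_median_E = stats::median(runs$random_search_E),
                 data_ss = problem$data_ss,
                 threshold_factor = threshold_factor),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "Recovery: %d runs, success rate %.2f (E < %g x data SS = %.4g)\n",
    nrow(x$runs), x$success_rate, x$threshold_factor,
    x$threshold_factor * x$data_ss))
  cat(sprintf("  ES median final E: %.4g", x$es_median_E))
  if (!all(is.na(x$runs$random_search_E)))
    cat(sprintf(" | random-search median: %.4g", x$rs_median_E))
  cat("\n")
  invisible(x)
}
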