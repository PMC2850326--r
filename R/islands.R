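# Multi-island execution: serial round-robin, synchronous-parallel
# (barrier) semantics, and asynchronous buffered exchange under a
# deterministic virtual-time scheduler.
#
# RNG discipline: every island owns a private evolution stream; migration
# receiver draws come from a dedicated stream (the master's schedule
# stream in serial/sync, a per-island migration stream in async), so the
# island streams consume identical draw sequences in every mode.  This is
# what makes synchronous-parallel runs bit-identical to serial runs with
# the same seed.

#' Termination specification
#'
#' Either a fixed number of generations, or "threshold hold": stop once
#' the best objective has remained at or below `threshold` for `hold`
#' consecutive log checks (i.e. `hold * tau` generations).
#'
#' @param mode `"fixed_generations"` or `"threshold_hold"`.
#' @param max_generations Generation cap (used by both modes; in
#'   threshold mode it is a safety cap).
#' @param threshold Target objective value E* (threshold mode).
#' @param hold Number of consecutive tau-checks the best must stay at or
#'   below `threshold` (rho).
#' @return An object of class `termination_spec`.
#' @export
termination_spec <- function(mode = c("fixed_generations",
                                      "threshold_hold"),
                             max_generations = 40000, threshold = NULL,
                             hold = NULL) {
  mode <- match.arg(mode)
  if (mode == "threshold_hold")
    stopifnot(is.numeric(threshold), is.numeric(hold), hold >= 1)
  structure(list(mode = mode,
                 max_generations = as.integer(max_generations),
                 threshold = threshold, hold = hold),
            class = "termination_spec")
}

#' Check a run log against a termination specification
#'
#' @param log Data frame with columns `generation` and `best_objective`
#'   (best-so-far, recorded every tau generations).
#' @param spec A [termination_spec()].
#' @return `TRUE` if the run should halt.
#' @export
check_termination <- function(log, spec) {
  if (nrow(log) == 0) return(FALSE)
  if (spec$mode == "fixed_generations")
    return(log$generation[nrow(log)] >= spec$max_generations)
  if (log$generation[nrow(log)] >= spec$max_generations) return(TRUE)
  below <- log$best_objective <= spec$threshold
  trailing <- 0L
  for (k in rev(seq_along(below))) {
    if (!below[k]) break
    trailing <- trailing + 1L
  }
  trailing >= spec$hold
}

#' Draw a migration schedule
#'
#' Every island is assigned a receiver island drawn uniformly from the
#' other islands; no island sends to itself.
#'
#' @param n_islands Number of islands (>= 2).
#' @param stream RNG stream for the draws (the master's).
#' @return Data frame (class `migration_schedule`) with columns `sender`
#'   and `receiver`.
#' @export
migration_schedule <- function(n_islands, stream) {
  stopifnot(n_islands >= 2)
  receivers <- with_stream(stream, vapply(seq_len(n_islands), function(i) {
    others <- setdiff(seq_len(n_islands), i)
    others[sample.int(n_islands - 1L, 1L)]
  }, integer(1)))
  structure(data.frame(sender = seq_len(n_islands), receiver = receivers),
            class = c("migration_schedule", "data.frame"))
}

# snapshot semantics: all bests are taken before any replacement
.apply_migration <- function(pops, schedule) {
  best_idx <- vapply(pops, function(p) which.min(p$fitness), integer(1))
  for (r in unique(schedule$receiver)) {
    senders <- schedule$sender[schedule$receiver == r]
    k <- length(senders)
    worst <- order(pops[[r]]$fitness, decreasing = TRUE)[seq_len(k)]
    for (j in seq_len(k)) {
      pops[[r]] <- .pop_replace(pops[[r]], worst[j],
                                pops[[senders[j]]], best_idx[senders[j]])
    }
  }
  pops
}

#' Serial-mode migration
#'
#' Each island's best individual is copied (the sender is unchanged) into
#' a uniformly chosen other island, replacing that island's worst
#' individual; an island chosen by several senders has its several worst
#' replaced. Bests are snapshotted before any replacement.
#'
#' @param islands List of evaluated populations.
#' @param stream RNG stream for the receiver draws.
#' @return Updated list of populations.
#' @export
serial_migrate <- function(islands, stream) {
  if (length(islands) < 2) return(islands)
  .apply_migration(islands, migration_schedule(length(islands), stream))
}

#' Synchronous-parallel migration
#'
#' The master builds a [migration_schedule()] and all islands exchange
#' point-to-point under barrier semantics. The replacement rule is the
#' same as [serial_migrate()]; with the same master stream the result is
#' identical.
#'
#' @param islands List of evaluated populations.
#' @param master_stream The master node's RNG stream.
#' @return Updated populations, with the schedule attached as attribute
#'   `schedule`.
#' @export
sync_migrate <- function(islands, master_stream) {
  if (length(islands) < 2) return(islands)
  sched <- migration_schedule(length(islands), master_stream)
  out <- .apply_migration(islands, sched)
  attr(out, "schedule") <- sched
  out
}

.make_clock <- function(clock) {
  if (is.null(clock)) {
    t0 <- proc.time()[[3]]
    function(tick) proc.time()[[3]] - t0
  } else {
    clock
  }
}

#' Run a multi-island Evolution Strategy
#'
#' Modes: `"serial"` iterates islands round-robin in one process;
#' `"sync"` models the synchronous-parallel algorithm (master migration
#' schedule, barrier exchange) and is bit-identical to `"serial"` for the
#' same seed; `"async"` runs islands under a deterministic virtual-time
#' scheduler with buffered migration and master-node statistics messages
#' (per-island start lags emulate heterogeneous node speeds).
#'
#' @param problem Problem list (e.g. [circuit_problem()] or
#'   [sphere_problem()]).
#' @param config An [es_config()].
#' @param mode `"serial"`, `"sync"` or `"async"`.
#' @param n_islands Number of islands (>= 1).
#' @param seed Base seed; island `i` uses `seed + i`, the master schedule
#'   stream `seed + 10007`, async migration streams `seed + 20011 + i`.
#' @param termination A [termination_spec()]; defaults to fixed
#'   generations at `config$max_generations`.
#' @param clock `NULL` for wall time, or `function(tick)` returning
#'   elapsed seconds for the given global generation tick (injectable for
#'   reproducible logs).
#' @param lag Integer vector of per-island start delays in ticks (async
#'   mode only; 0 = all islands in lockstep).
#' @param migrant_cap Max migrants one sender may leave in one island
#'   buffer (async; default 10). Full deposits are deferred, never
#'   dropped.
#' @param master_cap Max messages one sender may leave in the master
#'   buffer (async; default 50).
#' @return List with `best` (values, fitness, penalty), `log` (data frame
#'   `generation`, `elapsed_seconds`, `best_objective`,
#'   `n_evaluations`), `mode`, `n_islands`, `seed`, `generations`, and in
#'   async mode `counters` (message accounting).
#' @export
run_ies <- function(problem, config, mode = c("serial", "sync", "async"),
                    n_islands = 1, seed = 1, termination = NULL,
                    clock = NULL, lag = 0, migrant_cap = 10,
                    master_cap = 50) {
  mode <- match.arg(mode)
  stopifnot(n_islands >= 1)
  if (is.null(termination))
    termination <- termination_spec("fixed_generations",
                                    config$max_generations)
  if (mode == "async")
    .run_islands_async(problem, config, n_islands, seed, termination,
                       .make_clock(clock), lag, migrant_cap, master_cap)
  else
    .run_islands_lockstep(problem, config, mode, n_islands, seed,
                          termination, .make_clock(clock))
}

.run_islands_lockstep <- function(problem, config, mode, n_islands, seed,
                                  termination, clock_fn) {
  streams <- lapply(seq_len(n_islands),
                    function(i) rng_stream(seed + i))
  master <- rng_stream(seed + 10007L)
  pops <- lapply(streams, function(s) init_population(config, problem, s))
  n_evals <- n_islands * config$lambda_pop
  best_fit <- Inf
  best_values <- NULL
  best_penalty <- NA_real_
  for (p in pops) {
    i <- which.min(p$fitness)
    if (p$fitness[i] < best_fit) {
      best_fit <- p$fitness[i]
      best_values <- p$theta[i, ]
      best_penalty <- p$penalty[i]
    }
  }
  log_rows <- list()
  gen <- 0L
  max_gen <- termination$max_generations
  repeat {
    gen <- gen + 1L
    for (i in seq_len(n_islands)) {
      res <- generation_step(pops[[i]], config, problem, streams[[i]])
      pops[[i]] <- res$pop
      n_evals <- n_evals + res$stats$n_evaluations
      if (res$stats$best_fitness < best_fit) {
        best_fit <- res$stats$best_fitness
        best_values <- res$stats$best_values
        best_penalty <- problem$penalty(best_values)
      }
    }
    if (n_islands > 1 && gen %% config$migration_interval == 0) {
      pops <- if (mode == "sync") sync_migrate(pops, master)
              else serial_migrate(pops, master)
    }
    if (gen %% config$log_interval == 0) {
      log_rows[[length(log_rows) + 1]] <-
        data.frame(generation = gen, elapsed_seconds = clock_fn(gen),
                   best_objective = best_fit, n_evaluations = n_evals)
      log <- do.call(rbind, log_rows)
      if (check_termination(log, termination)) break
    }
    if (gen >= max_gen) break
  }
  list(best = list(values = best_values, fitness = best_fit,
                   penalty = best_penalty),
       log = do.call(rbind, log_rows), mode = mode,
       n_islands = n_islands, seed = seed, generations = gen,
       n_evaluations = n_evals)
}

.run_islands_async <- function(problem, config, n_islands, seed,
                               termination, clock_fn, lag, migrant_cap,
                               master_cap) {
  lag <- rep_len(as.integer(lag), n_islands)
  streams <- lapply(seq_len(n_islands),
                    function(i) rng_stream(seed + i))
  mig_streams <- lapply(seq_len(n_islands),
                        function(i) rng_stream(seed + 20011L + i))
  pops <- lapply(streams, function(s) init_population(config, problem, s))
  gen <- integer(n_islands)
  done <- rep(FALSE, n_islands)
  signalled <- rep(FALSE, n_islands)
  buffers <- vector("list", n_islands) # migrant entries: sender + individual
  for (i in seq_len(n_islands)) buffers[[i]] <- list()
  outbox <- vector("list", n_islands) # deferred migrant deposits
  for (i in seq_len(n_islands)) outbox[[i]] <- list()
  stats_outbox <- vector("list", n_islands) # deferred master messages
  for (i in seq_len(n_islands)) stats_outbox[[i]] <- list()
  master_buffer <- list()

  counters <- c(migrants_sent = 0, migrants_delivered = 0,
                migrant_deposits_deferred = 0, migrants_absorbed = 0,
                stats_sent = 0, stats_delivered = 0,
                stats_deposits_deferred = 0, signals_sent = 0)

  # per-island best-so-far (for master reports) + global best individual
  isl_best <- rep(Inf, n_islands)
  best_fit <- Inf
  best_values <- NULL
  n_evals <- n_islands * config$lambda_pop
  for (i in seq_len(n_islands)) {
    k <- which.min(pops[[i]]$fitness)
    isl_best[i] <- pops[[i]]$fitness[k]
    if (isl_best[i] < best_fit) {
      best_fit <- isl_best[i]
      best_values <- pops[[i]]$theta[k, ]
    }
  }

  # master bookkeeping: reports per tau-boundary, processed in order
  reports <- new.env(parent = emptyenv())
  next_boundary <- config$log_interval
  log_rows <- list()
  log_best <- Inf
  halted <- FALSE

  deposit_migrant <- function(sender, receiver, entry) {
    in_buf <- sum(vapply(buffers[[receiver]],
                         function(e) e$sender == sender, logical(1)))
    if (in_buf < migrant_cap) {
      buffers[[receiver]][[length(buffers[[receiver]]) + 1]] <<- entry
      counters["migrants_delivered"] <<- counters["migrants_delivered"] + 1
      TRUE
    } else {
      counters["migrant_deposits_deferred"] <<-
        counters["migrant_deposits_deferred"] + 1
      FALSE
    }
  }
  deposit_stats <- function(sender, entry) {
    in_buf <- sum(vapply(master_buffer,
                         function(e) e$sender == sender, logical(1)))
    if (in_buf < master_cap) {
      master_buffer[[length(master_buffer) + 1]] <<- entry
      counters["stats_delivered"] <<- counters["stats_delivered"] + 1
      TRUE
    } else {
      counters["stats_deposits_deferred"] <<-
        counters["stats_deposits_deferred"] + 1
      FALSE
    }
  }
  process_master <- function(tick, final = FALSE) {
    # drain the buffer, group reports by tau-boundary
    for (e in master_buffer) {
      key <- as.character(e$generation)
      rec <- get0(key, envir = reports,
                  ifnotfound = list(count = 0L, best = Inf))
      rec$count <- rec$count + 1L
      rec$best <- min(rec$best, e$best)
      assign(key, rec, envir = reports)
    }
    master_buffer <<- list()
    repeat {
      key <- as.character(next_boundary)
      rec <- get0(key, envir = reports, ifnotfound = NULL)
      expected <- sum(!vapply(seq_len(n_islands), function(i)
        done[i] && gen[i] < next_boundary, logical(1)))
      complete <- !is.null(rec) &&
        (rec$count >= expected || (final && rec$count > 0))
      if (!complete) break
      log_best <<- min(log_best, rec$best)
      log_rows[[length(log_rows) + 1]] <<-
        data.frame(generation = next_boundary,
                   elapsed_seconds = clock_fn(tick),
                   best_objective = log_best, n_evaluations = n_evals)
      next_boundary <<- next_boundary + config$log_interval
      log <- do.call(rbind, log_rows)
      if (!halted && check_termination(log, termination)) {
        halted <<- TRUE
        for (j in seq_len(n_islands)) {
          if (!done[j]) {
            signalled[j] <<- TRUE
            counters["signals_sent"] <<- counters["signals_sent"] + 1
          }
        }
      }
    }
  }

  max_gen <- termination$max_generations
  tick <- 0L
  while (!all(done)) {
    tick <- tick + 1L
    active <- which(!done & tick > lag)
    # phase A: each active island runs one generation
    for (i in active) {
      if (signalled[i]) {
        done[i] <- TRUE
        next
      }
      res <- generation_step(pops[[i]], config, problem, streams[[i]])
      pops[[i]] <- res$pop
      gen[i] <- gen[i] + 1L
      n_evals <- n_evals + res$stats$n_evaluations
      if (res$stats$best_fitness < isl_best[i])
        isl_best[i] <- res$stats$best_fitness
      if (res$stats$best_fitness < best_fit) {
        best_fit <- res$stats$best_fitness
        best_values <- res$stats$best_values
      }
      if (gen[i] >= max_gen) done[i] <- TRUE
    }
    active <- active[!signalled[active]]
    if (n_islands > 1) {
      at_migration <- active[gen[active] %% config$migration_interval == 0]
      # phase B: deposits (deferred ones first, then the fresh one)
      for (i in at_migration) {
        still <- list()
        for (e in outbox[[i]]) {
          if (!deposit_migrant(i, e$receiver, e$entry))
            still[[length(still) + 1]] <- e
        }
        outbox[[i]] <- still
        receiver <- with_stream(mig_streams[[i]], {
          others <- setdiff(seq_len(n_islands), i)
          others[sample.int(n_islands - 1L, 1L)]
        })
        k <- which.min(pops[[i]]$fitness)
        entry <- list(sender = i,
                      ind = .pop_subset(pops[[i]], k))
        counters["migrants_sent"] <- counters["migrants_sent"] + 1
        if (!deposit_migrant(i, receiver, entry))
          outbox[[i]][[length(outbox[[i]]) + 1]] <-
            list(receiver = receiver, entry = entry)
      }
      # phase C: absorb own buffer, then clear it
      for (i in at_migration) {
        if (length(buffers[[i]])) {
          for (e in buffers[[i]]) {
            pops[[i]] <- .pop_bind(pops[[i]], e$ind)
            counters["migrants_absorbed"] <-
              counters["migrants_absorbed"] + 1
          }
          buffers[[i]] <- list()
        }
      }
    }
    # phase D: statistics messages to the master buffer
    at_log <- active[gen[active] %% config$log_interval == 0]
    for (i in c(at_log)) {
      still <- list()
      for (e in stats_outbox[[i]]) {
        if (!deposit_stats(i, e)) still[[length(still) + 1]] <- e
      }
      stats_outbox[[i]] <- still
      entry <- list(sender = i, generation = gen[i], best = isl_best[i])
      counters["stats_sent"] <- counters["stats_sent"] + 1
      if (!deposit_stats(i, entry))
        stats_outbox[[i]][[length(stats_outbox[[i]]) + 1]] <- entry
    }
    # phase E: the master collects, logs and checks termination
    process_master(tick)
  }
  process_master(tick, final = TRUE)
  counters["migrants_pending_buffer"] <-
    sum(vapply(buffers, length, integer(1)))
  counters["migrants_pending_outbox"] <-
    sum(vapply(outbox, length, integer(1)))

  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(generation = integer(), elapsed_seconds = numeric(),
               best_objective = numeric(), n_evaluations = numeric())
  list(best = list(values = best_values, fitness = best_fit,
                   penalty = problem$penalty(best_values)),
       log = log, mode = "async", n_islands = n_islands, seed = seed,
       generations = max(gen), n_evaluations = n_evals,
       counters = counters)
}

#' Write a run log as tab-separated text
#'
#' Columns: generation, elapsed_seconds, best_objective, n_evaluations.
#'
#' @param log Run-log data frame from [run_ies()] or [run_sa()].
#' @param path Output path.
#' @param meta Optional named character vector of `#` header lines.
#' @export
write_runlog <- function(log, path, meta = NULL) {
  .write_tsv(log, path, meta)
}

#' Read a run log written by [write_runlog()]
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_runlog <- function(path) {
  lines <- readLines(path)
  utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                    header = TRUE)
}
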