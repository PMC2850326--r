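# Optimiser benchmarking metrics: mean descent curves, time-to-target
# with success rates, relative/absolute speed-up and Fieller confidence
# intervals for the ratio of mean times.

#' Mean descent curve over a set of runs
#'
#' Requires all logs to share the same generation grid. For each interval
#' the mean best-so-far objective, its standard error and the empirical
#' 95% range (2.5% and 97.5% quantiles) are returned.
#'
#' @param logs List of run-log data frames (columns `generation`,
#'   `elapsed_seconds`, `best_objective`).
#' @return Data frame of class `descent_curve` with columns `generation`,
#'   `mean_elapsed`, `mean_best`, `se`, `lo95`, `hi95`.
#' @export
descent_curve <- function(logs) {
  stopifnot(length(logs) >= 2)
  grid <- logs[[1]]$generation
  for (l in logs[-1]) {
    if (!identical(as.numeric(l$generation), as.numeric(grid)))
      stop("run logs are on mismatched generation grids")
  }
  vals <- vapply(logs, function(l) l$best_objective,
                 numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  elapsed <- vapply(logs, function(l) l$elapsed_seconds,
                    numeric(length(grid)))
  elapsed <- matrix(elapsed, nrow = length(grid))
  q <- t(apply(vals, 1, stats::quantile, probs = c(0.025, 0.975),
               names = FALSE))
  structure(data.frame(
    generation = grid,
    mean_elapsed = rowMeans(elapsed),
    mean_best = rowMeans(vals),
    se = apply(vals, 1, stats::sd) / sqrt(length(logs)),
    lo95 = q[, 1], hi95 = q[, 2]),
    class = c("descent_curve", "data.frame"))
}

#' Time-to-target statistics and success rate
#'
#' For each run, the first time (and generation) at which the best-so-far
#' objective reaches the target `E*`. The mean, standard error and normal
#' 95% confidence interval are computed over the runs that reached the
#' target; the success rate is the proportion of runs that reached it,
#' with an exact (Clopper-Pearson) binomial 95% confidence interval.
#'
#' @param logs List of run-log data frames.
#' @param target Target objective value E*.
#' @param time_col Column holding the time axis (default
#'   `"elapsed_seconds"`).
#' @return An object of class `target_stats`.
#' @export
time_to_target <- function(logs, target, time_col = "elapsed_seconds") {
  times <- vapply(logs, function(l) {
    hit <- which(l$best_objective <= target)
    if (length(hit)) l[[time_col]][hit[1]] else NA_real_
  }, numeric(1))
  n_attempts <- length(logs)
  reached <- times[!is.na(times)]
  n_reached <- length(reached)
  bt <- stats::binom.test(n_reached, n_attempts)
  if (n_reached > 0) {
    mean_t <- mean(reached)
    se <- if (n_reached > 1) stats::sd(reached) / sqrt(n_reached) else 0
    ci <- mean_t + c(-1, 1) * stats::qnorm(0.975) * se
  } else {
    mean_t <- NA_real_
    se <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(target = target, n_attempts = n_attempts,
                 n_reached = n_reached, times = times,
                 mean_time = mean_t, se = se, ci95 = ci,
                 success_rate = n_reached / n_attempts,
                 success_ci95 = as.numeric(bt$conf.int)),
            class = "target_stats")
}

#' @export
print.target_stats <- function(x, ...) {
  cat(sprintf("Target %g: %d/%d runs reached (rate %.2f, 95%% CI %.3f-%.3f)\n",
              x$target, x$n_reached, x$n_attempts, x$success_rate,
              x$success_ci95[1], x$success_ci95[2]))
  if (x$n_reached > 0)
    cat(sprintf("  mean time %.4g (SE %.3g, 95%% CI %.4g-%.4g)\n",
                x$mean_time, x$se, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Fieller confidence interval for a ratio of Gaussian means
#'
#' Interval for `num_mean / den_mean` assuming independent Gaussian
#' estimates with the given standard errors (zero covariance). When the
#' denominator is not significantly nonzero at the requested confidence
#' the interval is unbounded and `bounded` is `FALSE`.
#'
#' @param num_mean,num_se Numerator mean and standard error.
#' @param den_mean,den_se Denominator mean and standard error.
#' @param confidence Confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper`, `bounded`.
#' @export
fieller_ci <- function(num_mean, num_se, den_mean, den_se,
                       confidence = 0.95) {
  if (num_se < 0 || den_se < 0) stop("standard errors must be >= 0")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  est <- num_mean / den_mean
  if (den_se == 0) {
    ci <- sort((num_mean + c(-1, 1) * z * num_se) / den_mean)
    return(list(estimate = est, lower = ci[1], upper = ci[2],
                bounded = TRUE))
  }
  g <- (z * den_se / den_mean)^2
  if (g >= 1) {
    return(list(estimate = est, lower = -Inf, upper = Inf,
                bounded = FALSE))
  }
  disc <- num_se^2 + est^2 * den_se^2 - g * num_se^2
  half <- (z / abs(den_mean)) * sqrt(disc)
  list(estimate = est,
       lower = (est - half) / (1 - g),
       upper = (est + half) / (1 - g),
       bounded = TRUE)
}

#' Parallel speed-up with Fieller confidence interval
#'
#' Relative speed-up compares the serial algorithm with K islands against
#' the parallel algorithm on K nodes (a measure of communication
#' overhead); absolute speed-up compares the best serial configuration
#' (K* islands) against the parallel algorithm on K nodes (the practical
#' gain).
#'
#' @param serial_mean,serial_se Mean time-to-target (and SE) of the
#'   serial reference: the K-island serial run for `kind = "relative"`,
#'   the K*-island serial run for `kind = "absolute"`.
#' @param parallel_mean,parallel_se Mean time-to-target (and SE) of the
#'   parallel run on K nodes.
#' @param kind `"relative"` or `"absolute"` (label only; the arithmetic
#'   is the ratio of the supplied means).
#' @param confidence Confidence level for the Fieller interval.
#' @return List with `speedup`, `lower`, `upper`, `bounded`, `kind`.
#' @export
speedup <- function(serial_mean, serial_se, parallel_mean, parallel_se,
                    kind = c("relative", "absolute"), confidence = 0.95) {
  kind <- match.arg(kind)
  if (parallel_mean == 0) stop("parallel mean time is zero")
  ci <- fieller_ci(serial_mean, serial_se, parallel_mean, parallel_se,
                   confidence)
  list(speedup = ci$estimate, lower = ci$lower, upper = ci$upper,
       bounded = ci$bounded, kind = kind)
}

#' Parse an hours:minutes duration
#'
#' `"3:35"` becomes 3.5833 hours. Values like `">36:00"` give `NA` with
#' attribute `censored`.
#'
#' @param x Character vector of `H:MM` durations.
#' @return Numeric hours.
#' @export
parse_hm <- function(x) {
  x <- trimws(x)
  censored <- startsWith(x, ">")
  x2 <- sub("^>", "", x)
  parts <- strsplit(x2, ":", fixed = TRUE)
  out <- vapply(parts, function(p) {
    if (length(p) != 2 || anyNA(suppressWarnings(as.numeric(p))))
      return(NA_real_)
    as.numeric(p[1]) + as.numeric(p[2]) / 60
  }, numeric(1))
  out[censored] <- NA_real_
  attr(out, "censored") <- censored
  out
}

#' Load the published gap-gene benchmark run times
#'
#' Reads the packaged table of previously reported wall-clock times for
#' the gap-gene reverse-engineering benchmark (serial island-ES with
#' 1-50 islands; synchronous and asynchronous parallel island-ES and
#' 10-50 nodes). Durations are `H:MM` strings; the half-width columns
#' record the printed uncertainty as parsed (the `interval`
#' interpretation flag is carried along, as published intervals mix SE
#' and 95% CI conventions).
#'
#' @param path Optional path to an alternative TSV.
#' @return Data frame with times converted to hours.
#' @export
published_runtimes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gap_gene_benchmark_times.tsv",
                        package = "gcies", mustWork = TRUE)
  lines <- readLines(path)
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  for (col in c("time_good_enough", "hw_good_enough", "time_good",
                "hw_good")) {
    parsed <- parse_hm(df[[col]])
    df[[paste0(col, "_h")]] <- as.numeric(parsed)
  }
  df
}

#' Speed-up table from published benchmark times
#'
#' Recomputes relative speed-up (serial K-island time over parallel
#' K-node time) and absolute speed-up (serial K*-island time over
#' parallel K-node time) for each parallel row of the published benchmark
#' table, with Fieller confidence intervals computed from the printed
#' half-widths treated as 95% CIs on the mean.
#'
#' @param runtimes Data frame from [published_runtimes()].
#' @param target `"good_enough"` (E* = 550000) or `"good"`
#'   (E* = 350000).
#' @param k_star Number of islands of the best serial configuration
#'   (default 1).
#' @return Data frame with one row per parallel configuration.
#' @export
speedup_table <- function(runtimes, target = c("good_enough", "good"),
                          k_star = 1) {
  target <- match.arg(target)
  tcol <- paste0("time_", target, "_h")
  hcol <- paste0("hw_", target, "_h")
  z <- stats::qnorm(0.975)
  serial <- runtimes[runtimes$algorithm == "serial", ]
  par <- runtimes[runtimes$algorithm != "serial", ]
  ref_star <- serial[serial$nodes == k_star, ]
  rows <- lapply(seq_len(nrow(par)), function(r) {
    K <- par$nodes[r]
    ref_k <- serial[serial$nodes == K, ]
    rel <- if (nrow(ref_k) == 1 && is.finite(ref_k[[tcol]])) {
      speedup(ref_k[[tcol]], ref_k[[hcol]] / z,
              par[[tcol]][r], par[[hcol]][r] / z, "relative")
    } else {
      # no serial run with a matching island count was reported
      list(speedup = NA_real_, lower = NA_real_, upper = NA_real_)
    }
    abs_ <- speedup(ref_star[[tcol]], ref_star[[hcol]] / z,
                    par[[tcol]][r], par[[hcol]][r] / z, "absolute")
    data.frame(algorithm = par$algorithm[r], nodes = K,
               time_h = par[[tcol]][r],
               relative_speedup = rel$speedup,
               relative_lo = rel$lower, relative_hi = rel$upper,
               absolute_speedup = abs_$speedup,
               absolute_lo = abs_$lower, absolute_hi = abs_$upper)
  })
  do.call(rbind, rows)
}
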