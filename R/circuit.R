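# Connectionist gene-circuit model: domain types and simulation.
#
# The model follows the gap-gene gene-circuit formalism: protein
# concentrations g_i^a in a 1-D row of nuclei i obey
#
#   dg_i^a/dt = R^a Phi(u_i^a) + D^a(n) [neighbour differences] - lambda^a g_i^a
#   u_i^a     = sum_b W^{ab} g_i^b + m^a bcd_i + h^a
#
# with Phi the sigmoid regulation-expression function, Bcd an external
# input, zero-flux diffusion boundaries, and a mitotic schedule that
# switches production off during mitosis and doubles the nuclei (and
# quadruples the effective diffusion rate, D^a(n) = 4 D^a(n-1)) at each
# instantaneous division.

#' Gene circuit parameters
#'
#' @param W Square numeric matrix (`N_g` x `N_g`); `W[a, b]` is the
#'   regulatory weight of gene `b` on gene `a` (positive = activation,
#'   negative = repression).
#' @param m Numeric vector of Bcd regulatory weights, one per gene.
#' @param h Numeric vector of threshold parameters, one per gene.
#' @param R Strictly positive maximum production rates (concentration/min).
#' @param D_base Non-negative diffusion rates at division count 0 (1/min).
#' @param decay Strictly positive decay rates lambda (1/min); the protein
#'   half-life is `log(2) / decay`.
#' @param genes Optional character vector of gene names.
#' @param sigmoid Form of the regulation-expression function: `"ratio"`
#'   (default, `(u / sqrt(u^2 + 1) + 1) / 2`) or `"logistic"`.
#' @return An object of class `gene_circuit_params`.
#' @export
gene_circuit_params <- function(W, m, h, R, D_base, decay, genes = NULL,
                                sigmoid = c("ratio", "logistic")) {
  sigmoid <- match.arg(sigmoid)
  W <- as.matrix(W)
  G <- nrow(W)
  if (ncol(W) != G)
    stop("W must be square; got ", G, " x ", ncol(W))
  for (nm in c("m", "h", "R", "D_base", "decay")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != G || any(!is.finite(v)))
      stop("field '", nm, "' must be a finite numeric vector of length ", G)
  }
  if (any(R <= 0)) stop("field 'R' must be strictly positive")
  if (any(decay <= 0)) stop("field 'decay' must be strictly positive")
  if (any(D_base < 0)) stop("field 'D_base' must be non-negative")
  if (is.null(genes)) genes <- paste0("gene", seq_len(G))
  if (length(genes) != G) stop("field 'genes' must have length ", G)
  structure(
    list(W = unname(W), m = unname(m), h = unname(h), R = unname(R),
         D_base = unname(D_base), decay = unname(decay),
         genes = genes, sigmoid = sigmoid),
    class = "gene_circuit_params")
}

#' @export
print.gene_circuit_params <- function(x, ...) {
  cat("Gene circuit with", length(x$genes), "genes:",
      paste(x$genes, collapse = ", "), "\n")
  cat("  half-lives (min):",
      paste(signif(log(2) / x$decay, 3), collapse = ", "), "\n")
  invisible(x)
}

n_genes <- function(params) length(params$genes)

#' Mitotic schedule
#'
#' An ordered sequence of phases: interphase (full dynamics), mitosis
#' (production switched off) and division (instantaneous, zero duration).
#' Phases must be contiguous and non-overlapping with strictly increasing
#' time, and divisions may occur only at phase boundaries.
#'
#' @param kind Character vector in `c("interphase", "mitosis", "division")`.
#' @param start,end Numeric phase boundaries in minutes.
#' @return A data frame of class `mitotic_schedule`.
#' @export
mitotic_schedule <- function(kind, start, end) {
  kind <- match.arg(kind, c("interphase", "mitosis", "division"),
                    several.ok = TRUE)
  if (length(kind) != length(start) || length(kind) != length(end))
    stop("kind, start and end must have equal length")
  if (any(end < start)) stop("phase end before start")
  dur <- end - start
  if (any(kind == "division" & dur != 0))
    stop("division events must have zero duration")
  if (any(kind != "division" & dur <= 0))
    stop("continuous phases must have positive duration")
  if (length(kind) > 1 &&
      any(abs(start[-1] - end[-length(end)]) > 1e-9))
    stop("phases must be contiguous")
  structure(data.frame(kind = kind, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("mitotic_schedule", "data.frame"))
}

schedule_span <- function(schedule) c(schedule$start[1],
                                      schedule$end[nrow(schedule)])

n_divisions <- function(schedule) sum(schedule$kind == "division")

.schedule_kind_codes <- c(interphase = 0L, mitosis = 1L, division = 2L)

#' Embryo state
#'
#' Concentrations of all gene products in all nuclei at one instant, plus
#' the division counter and the Bcd input profile.
#'
#' @param conc Non-negative numeric matrix, nuclei x genes.
#' @param n_div Number of divisions that have occurred so far.
#' @param bcd Non-negative Bcd concentration per nucleus.
#' @param time Time in minutes.
#' @return An object of class `embryo_state`.
#' @export
embryo_state <- function(conc, n_div = 0L, bcd = NULL, time = 0) {
  conc <- as.matrix(conc)
  if (is.null(bcd)) bcd <- rep(0, nrow(conc))
  if (length(bcd) != nrow(conc))
    stop("field 'bcd' must have one value per nucleus (",
         nrow(conc), "); got ", length(bcd))
  if (any(conc < 0)) stop("field 'conc' must be non-negative")
  if (any(bcd < 0)) stop("field 'bcd' must be non-negative")
  if (n_div < 0 || n_div != round(n_div))
    stop("field 'n_div' must be a non-negative integer")
  structure(list(conc = unname(conc), n_div = as.integer(n_div),
                 bcd = as.numeric(bcd), time = as.numeric(time)),
            class = "embryo_state")
}

#' Total regulatory input u^a for one nucleus
#'
#' `u^a = sum_b W[a, b] conc[b] + m[a] * bcd + h[a]`.
#'
#' @param params A [gene_circuit_params()].
#' @param conc Concentration vector of length `N_g` for one nucleus.
#' @param bcd Scalar Bcd concentration in that nucleus.
#' @return Numeric vector of length `N_g`.
#' @export
regulatory_input <- function(params, conc, bcd) {
  G <- n_genes(params)
  if (length(conc) != G)
    stop("field 'conc' must have length ", G, "; got ", length(conc))
  if (length(bcd) != 1)
    stop("field 'bcd' must be a scalar")
  drop(params$W %*% conc) + params$m * bcd + params$h
}

#' Regulation-expression sigmoid
#'
#' The default form is `Phi(u) = (u / sqrt(u^2 + 1) + 1) / 2`, strictly
#' increasing from 0 to 1 with `Phi(0) = 1/2`.
#'
#' @param u Finite numeric vector.
#' @param form `"ratio"` (default) or `"logistic"`.
#' @export
sigmoid_phi <- function(u, form = c("ratio", "logistic")) {
  form <- match.arg(form)
  if (any(!is.finite(u))) stop("'u' must be finite")
  switch(form,
         ratio = 0.5 * (u / sqrt(u^2 + 1) + 1),
         logistic = 1 / (1 + exp(-u)))
}

#' Right-hand side of the circuit ODEs
#'
#' Returns `dg/dt` for every nucleus and gene under the continuous rule of
#' the given phase: production is active during interphase and exactly
#' zero during mitosis; diffusion uses the effective rate
#' `D^a(n) = 4^n D_base^a` and zero-flux boundaries.
#'
#' @param state An [embryo_state()].
#' @param params A [gene_circuit_params()].
#' @param phase `"interphase"` or `"mitosis"`.
#' @return Numeric matrix, nuclei x genes.
#' @export
circuit_rhs <- function(state, params, phase = c("interphase", "mitosis")) {
  phase <- match.arg(phase)
  .check_state(state, params)
  .cpp_circuit_rhs(state$conc, state$bcd, unclass(params), state$n_div,
                   phase == "interphase")
}

.check_state <- function(state, params) {
  if (!inherits(state, "embryo_state")) stop("not an embryo_state")
  if (nrow(state$conc) < 1) stop("empty state")
  if (ncol(state$conc) != n_genes(params))
    stop("state has ", ncol(state$conc), " genes; params have ",
         n_genes(params))
  if (any(state$conc < -1e-8))
    stop("negative concentrations in state")
  invisible(TRUE)
}

#' Apply the discrete division rule
#'
#' Each nucleus splits into two daughters that copy the mother's
#' concentrations; the division counter is incremented, so the effective
#' diffusion rate quadruples. The Bcd profile for the new epoch must be
#' supplied (Bcd is an external input, not a state variable); it defaults
#' to duplicating the mother's value.
#'
#' @param state An [embryo_state()].
#' @param bcd_new Optional Bcd vector of length `2 * N_nuc`.
#' @return The post-division [embryo_state()].
#' @export
apply_division <- function(state, bcd_new = NULL) {
  conc2 <- state$conc[rep(seq_len(nrow(state$conc)), each = 2), ,
                      drop = FALSE]
  if (is.null(bcd_new)) bcd_new <- rep(state$bcd, each = 2)
  if (length(bcd_new) != nrow(conc2))
    stop("field 'bcd' must have ", nrow(conc2), " values after division")
  embryo_state(conc2, state$n_div + 1L, bcd_new, state$time)
}

#' Integrate the circuit ODEs over a division-free interval
#'
#' Adaptive Bulirsch-Stoer integration (modified midpoint with Richardson
#' extrapolation) with local relative error controlled at `rtol`.
#'
#' @param state An [embryo_state()] at time `t0`.
#' @param params A [gene_circuit_params()].
#' @param phase Continuous rule to apply, `"interphase"` or `"mitosis"`.
#' @param t0,t1 Interval in minutes, `t1 > t0`.
#' @param rtol Relative error tolerance (default `1e-3`).
#' @return The [embryo_state()] at `t1`.
#' @export
integrate_interval <- function(state, params,
                               phase = c("interphase", "mitosis"),
                               t0 = state$time, t1, rtol = 1e-3) {
  phase <- match.arg(phase)
  .check_state(state, params)
  if (t1 <= t0) stop("t1 must exceed t0")
  conc <- .cpp_integrate_interval(state$conc, state$bcd, unclass(params),
                                  state$n_div, phase == "interphase",
                                  t0, t1, rtol)
  embryo_state(pmax(conc, 0), state$n_div, state$bcd, t1)
}

#' Simulate a gene circuit over a mitotic schedule
#'
#' Alternates continuous integration (interphase and mitosis rules) with
#' the discrete division rule, and records the state at each requested
#' output time. An output time that coincides with a division instant
#' yields the post-division state.
#'
#' @param params A [gene_circuit_params()].
#' @param initial An [embryo_state()] at the schedule start.
#' @param schedule A [mitotic_schedule()].
#' @param output_times Sorted times within the schedule span.
#' @param bcd_profiles List of Bcd vectors, one per division epoch
#'   (element 1 = epoch of the initial state); defaults to a single-epoch
#'   list built from `initial$bcd` when the schedule has no divisions.
#' @param rtol Solver relative tolerance.
#' @return A `circuit_trajectory`: list with `times` and `states` (a list
#'   of [embryo_state()]).
#' @export
simulate_circuit <- function(params, initial, schedule, output_times,
                             bcd_profiles = NULL, rtol = 1e-3) {
  stopifnot(inherits(schedule, "mitotic_schedule"))
  .check_state(initial, params)
  span <- schedule_span(schedule)
  if (abs(initial$time - span[1]) > 1e-9)
    stop("initial state time ", initial$time,
         " does not match schedule start ", span[1])
  if (is.unsorted(output_times))
    stop("output_times must be sorted")
  if (any(output_times < span[1] - 1e-9) ||
      any(output_times > span[2] + 1e-9))
    stop("output_times must lie within the schedule span [",
         span[1], ", ", span[2], "]")
  if (is.null(bcd_profiles)) {
    if (n_divisions(schedule) > 0)
      stop("bcd_profiles must be supplied for schedules with divisions")
    bcd_profiles <- list(initial$bcd)
  }
  if (length(bcd_profiles) != n_divisions(schedule) + 1)
    stop("need ", n_divisions(schedule) + 1, " Bcd profiles; got ",
         length(bcd_profiles))
  sim <- .cpp_simulate(unclass(params), initial$conc, initial$n_div,
                       bcd_profiles,
                       .schedule_kind_codes[schedule$kind],
                       schedule$start, schedule$end,
                       as.numeric(output_times), rtol)
  states <- vector("list", length(output_times))
  for (k in seq_along(output_times)) {
    nd <- sim$n_div[k]
    epoch <- nd - initial$n_div + 1L
    states[[k]] <- embryo_state(pmax(sim$conc[[k]], 0), nd,
                                bcd_profiles[[epoch]], output_times[k])
  }
  structure(list(times = as.numeric(output_times), states = states,
                 genes = params$genes),
            class = "circuit_trajectory")
}

#' Export a trajectory as tab-separated text
#'
#' Columns: time, nucleus_index, ap_position_percent, then one column per
#' gene. A-P positions are spaced evenly over the modelled region for the
#' nucleus count of each epoch.
#'
#' @param traj A `circuit_trajectory` from [simulate_circuit()].
#' @param path Output file path.
#' @param ap_range A-P window carried as metadata (percent egg length).
#' @param meta Optional named character vector written as `#` header lines.
#' @export
write_trajectory <- function(traj, path, ap_range = c(35, 92), meta = NULL) {
  rows <- lapply(traj$states, function(st) {
    N <- nrow(st$conc)
    df <- data.frame(time = st$time, nucleus_index = seq_len(N),
                     ap_position_percent = ap_positions(N, ap_range))
    conc <- as.data.frame(st$conc)
    names(conc) <- traj$genes
    cbind(df, conc)
  })
  .write_tsv(do.call(rbind, rows), path, meta)
}

#' Evenly spaced A-P positions (percent egg length)
#'
#' @param n_nuc Number of nuclei.
#' @param ap_range Modelled window along the A-P axis.
#' @export
ap_positions <- function(n_nuc, ap_range = c(35, 92)) {
  seq(ap_range[1], ap_range[2], length.out = n_nuc)
}

.write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), ": ", unname(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
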