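# Objective, penalty and search-space constraints.
#
# The objective E(theta) is the unweighted sum of squared differences
# between simulated and observed concentrations over all observed
# (time class, gene, nucleus) cells.  Regulatory parameters (W, m, h)
# carry a soft penalty that is exactly zero while the worst-case total
# regulatory input stays inside a band set by the control parameter
# Lambda, and grows steeply outside it.  Kinetic parameters (R, D,
# half-life) have hard box bounds: values outside are unacceptable and
# rejected.

#' Search-space definition
#'
#' @param Lambda Penalty control parameter (default `1e-4`). The penalty
#'   is zero while the worst-case total regulatory input of each gene
#'   stays below `1 / sqrt(Lambda)`.
#' @param R_range Open interval for production rates (default `(10, 30)`).
#' @param D_range Open interval for diffusion rates (default `(0, 0.3)`).
#' @param halflife_range Open interval for protein half-lives in minutes
#'   (default `(5, 20)`), i.e. `5 < log(2)/lambda < 20`.
#' @param h_fixed Threshold fixing: `NULL` estimates every `h^a` freely;
#'   a scalar (default `-2.5`) fixes all thresholds to that value; a
#'   numeric vector of length `N_g` fixes gene `a`'s threshold to
#'   `h_fixed[a]`, with `NA` entries left free (this is how a 6-gene
#'   circuit drops from 66 to 62 free parameters when four thresholds
#'   are pinned at -2.5).
#' @return An object of class `search_space`.
#' @export
search_space <- function(Lambda = 1e-4, R_range = c(10, 30),
                         D_range = c(0, 0.3), halflife_range = c(5, 20),
                         h_fixed = -2.5) {
  stopifnot(Lambda > 0, diff(R_range) > 0, diff(D_range) > 0,
            diff(halflife_range) > 0)
  if (!is.null(h_fixed)) stopifnot(is.numeric(h_fixed))
  structure(list(Lambda = Lambda, R_range = R_range, D_range = D_range,
                 halflife_range = halflife_range, h_fixed = h_fixed),
            class = "search_space")
}

# which thresholds remain free parameters under a space's h_fixed rule
.h_free_idx <- function(h_fixed, G) {
  if (is.null(h_fixed)) return(seq_len(G))
  if (length(h_fixed) == 1 && !is.na(h_fixed)) return(integer(0))
  if (length(h_fixed) != G)
    stop("h_fixed must be NULL, a scalar, or a length-", G, " vector")
  which(is.na(h_fixed))
}

# full threshold vector: fixed entries from the rule, free ones from theta
.h_full <- function(values, layout, h_fixed, G) {
  free <- attr(layout, "h_free")
  h <- if (is.null(h_fixed)) rep(NA_real_, G) else rep_len(h_fixed, G)
  if (length(free)) h[free] <- values[layout$h]
  h
}

# slice indices of the flat parameter vector; order: W rows, m, (free h),
# R, D_base, decay
.pv_layout <- function(G, h_free_idx) {
  at <- 0L
  take <- function(k) {
    idx <- at + seq_len(k)
    at <<- at + k
    idx
  }
  layout <- list(W = take(G * G), m = take(G))
  if (length(h_free_idx)) layout$h <- take(length(h_free_idx))
  layout$R <- take(G)
  layout$D_base <- take(G)
  layout$decay <- take(G)
  attr(layout, "n") <- at
  attr(layout, "G") <- G
  attr(layout, "h_free") <- h_free_idx
  layout
}

#' Pack circuit parameters into a flat vector
#'
#' Order: the rows of `W` (regulators of gene 1, gene 2, ...), then `m`,
#' then the free entries of `h`, then `R`, `D_base`, `decay`. With `N_g`
#' genes the length is `N_g * (N_g + 5)` when all thresholds are free,
#' `N_g * (N_g + 4)` when all are fixed, and in between when only some
#' are fixed (a 6-gene circuit with four thresholds pinned packs 62
#' parameters).
#'
#' @param params A [gene_circuit_params()].
#' @param space A [search_space()]; its `h_fixed` decides whether `h` is
#'   packed.
#' @return An object of class `parameter_vector` with fields `values`,
#'   `layout`, `genes`, `h_fixed`, `sigmoid`.
#' @export
pack_parameters <- function(params, space = search_space()) {
  G <- n_genes(params)
  h_free <- .h_free_idx(space$h_fixed, G)
  layout <- .pv_layout(G, h_free)
  values <- numeric(attr(layout, "n"))
  values[layout$W] <- as.vector(t(params$W)) # row-major: gene a's regulators
  values[layout$m] <- params$m
  if (length(h_free)) values[layout$h] <- params$h[h_free]
  values[layout$R] <- params$R
  values[layout$D_base] <- params$D_base
  values[layout$decay] <- params$decay
  structure(list(values = values, layout = layout, genes = params$genes,
                 h_fixed = space$h_fixed, sigmoid = params$sigmoid),
            class = "parameter_vector")
}

#' Unpack a flat parameter vector
#'
#' @param theta A `parameter_vector`, or a bare numeric vector (then
#'   `genes` and `space` must be given).
#' @param genes Gene names (when `theta` is bare).
#' @param space A [search_space()] (when `theta` is bare).
#' @param sigmoid Sigmoid form for the rebuilt circuit.
#' @return A [gene_circuit_params()].
#' @export
unpack_parameters <- function(theta, genes = NULL, space = NULL,
                              sigmoid = "ratio") {
  if (inherits(theta, "parameter_vector")) {
    values <- theta$values
    layout <- theta$layout
    genes <- theta$genes
    h_fixed <- theta$h_fixed
    sigmoid <- theta$sigmoid
  } else {
    stopifnot(!is.null(genes), !is.null(space))
    layout <- .pv_layout(length(genes),
                         .h_free_idx(space$h_fixed, length(genes)))
    if (length(theta) != attr(layout, "n"))
      stop("parameter vector has length ", length(theta),
           "; expected ", attr(layout, "n"))
    values <- as.numeric(theta)
    h_fixed <- space$h_fixed
  }
  G <- attr(layout, "G")
  h <- .h_full(values, layout, h_fixed, G)
  gene_circuit_params(
    W = matrix(values[layout$W], G, G, byrow = TRUE),
    m = values[layout$m], h = h, R = values[layout$R],
    D_base = values[layout$D_base], decay = values[layout$decay],
    genes = genes, sigmoid = sigmoid)
}

#' Hard search-space bounds check
#'
#' Acceptable iff, strictly, `10 < R^a < 30`, `0 < D^a < 0.3` and
#' `5 < log(2)/lambda^a < 20` for every gene (defaults; taken from
#' `space`). Regulatory parameters are unconstrained here (they are
#' handled by the soft penalty).
#'
#' @param theta A `parameter_vector` or bare numeric vector.
#' @param space A [search_space()].
#' @param genes Gene names when `theta` is bare.
#' @return List with `acceptable` (logical) and `violations` (data frame
#'   with columns `param`, `gene`, `value`).
#' @export
check_hard_bounds <- function(theta, space = search_space(), genes = NULL) {
  if (inherits(theta, "parameter_vector")) {
    layout <- theta$layout
    values <- theta$values
    gene_names <- theta$genes
  } else {
    stopifnot(!is.null(genes))
    layout <- .pv_layout(length(genes),
                         .h_free_idx(space$h_fixed, length(genes)))
    values <- as.numeric(theta)
    gene_names <- genes
  }
  G <- attr(layout, "G")
  viol <- list()
  note <- function(param, ok, vals) {
    bad <- which(!ok)
    if (length(bad))
      viol[[length(viol) + 1]] <<- data.frame(
        param = param, gene = gene_names[bad], value = vals[bad],
        stringsAsFactors = FALSE)
  }
  R <- values[layout$R]
  D <- values[layout$D_base]
  lam <- values[layout$decay]
  hl <- log(2) / lam
  note("R", R > space$R_range[1] & R < space$R_range[2], R)
  note("D", D > space$D_range[1] & D < space$D_range[2], D)
  note("halflife", lam > 0 & hl > space$halflife_range[1] &
         hl < space$halflife_range[2], hl)
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(param = character(), gene = character(), value = numeric())
  list(acceptable = nrow(violations) == 0, violations = violations)
}

#' Soft penalty on regulatory parameters
#'
#' For each gene `a` the worst-case total regulatory input over the data
#' range is `u_cap^a = sum_b |W[a,b]| v_max^b + |m^a| bcd_max + |h^a|`,
#' where `v_max^b` is the maximum observed intensity of gene `b`. The
#' penalty is `sum_a max(0, Lambda * (u_cap^a)^2 - 1)`: exactly zero
#' while `u_cap^a <= 1/sqrt(Lambda)` for every gene, continuous, and
#' strictly increasing once any regulatory parameter scales beyond that
#' band. Kinetic parameters (R, D, decay) never contribute.
#'
#' @param theta A `parameter_vector`, or bare vector with `genes`/`space`.
#' @param gene_maxima Per-gene maximum observed intensity.
#' @param bcd_max Maximum Bcd input level.
#' @param Lambda Control parameter (default from `space`, `1e-4`).
#' @param space,genes Used when `theta` is a bare vector.
#' @return Non-negative penalty value.
#' @export
penalty_regulatory <- function(theta, gene_maxima, bcd_max,
                               Lambda = 1e-4, space = NULL, genes = NULL) {
  if (inherits(theta, "parameter_vector")) {
    layout <- theta$layout
    values <- theta$values
    h_fixed <- theta$h_fixed
  } else {
    stopifnot(!is.null(genes), !is.null(space))
    layout <- .pv_layout(length(genes),
                         .h_free_idx(space$h_fixed, length(genes)))
    values <- as.numeric(theta)
    h_fixed <- space$h_fixed
  }
  G <- attr(layout, "G")
  stopifnot(length(gene_maxima) == G, all(gene_maxima > 0))
  W <- matrix(values[layout$W], G, G, byrow = TRUE)
  m <- values[layout$m]
  h <- .h_full(values, layout, h_fixed, G)
  u_cap <- drop(abs(W) %*% gene_maxima) + abs(m) * bcd_max + abs(h)
  sum(pmax(0, Lambda * u_cap^2 - 1))
}

#' Least-squares objective E(theta)
#'
#' Simulates the circuit from the data set's initial state over the
#' mitotic schedule and returns the sum of squared differences between
#' model output and data over all observed cells of the fitted time
#' classes (the earliest class is the initial condition and is excluded).
#' All observations are weighted equally.
#'
#' @param theta A `parameter_vector` or bare numeric vector.
#' @param dataset An [expression_dataset()].
#' @param schedule A [mitotic_schedule()] covering the data's time span.
#' @param space A [search_space()] (needed when `theta` is bare).
#' @param rtol Solver relative tolerance.
#' @return Non-negative sum of squares; `Inf` if the solver fails (global
#'   searches visit pathological parameter sets, so failures are treated
#'   as infinitely poor fits rather than errors).
#' @export
objective_E <- function(theta, dataset, schedule, space = search_space(),
                        rtol = 1e-3) {
  problem <- circuit_problem(dataset, schedule, space, rtol)
  values <- if (inherits(theta, "parameter_vector")) theta$values else theta
  problem$objective(values)
}

#' Build an optimisation problem from a data set
#'
#' Pre-compiles the simulation inputs and observation index so that the
#' objective can be evaluated cheaply inside an optimiser loop.
#'
#' @param dataset An [expression_dataset()].
#' @param schedule A [mitotic_schedule()].
#' @param space A [search_space()].
#' @param rtol Solver relative tolerance.
#' @param sigmoid Sigmoid form used in simulation.
#' @return A list with fields `n`, `objective(values)`, `penalty(values)`,
#'   `feasible(values)`, `sample_init(k, stream)`, `sigma0`, `data_ss`
#'   (sum of squared fitted observations), `genes`, `space`, `layout`.
#' @export
circuit_problem <- function(dataset, schedule, space = search_space(),
                            rtol = 1e-3, sigmoid = "ratio") {
  genes <- dataset$genes
  G <- length(genes)
  h_free <- .h_free_idx(space$h_fixed, G)
  layout <- .pv_layout(G, h_free)
  n <- attr(layout, "n")
  fit_times <- dataset$times[-1]
  if (length(fit_times) == 0) stop("dataset has no fitted time classes")
  span <- schedule_span(schedule)
  if (max(fit_times) > span[2] + 1e-9)
    stop("schedule ends before the last time class")
  # epoch bookkeeping for the simulation
  n_div0 <- dataset$initial$n_div
  epochs <- sort(as.integer(names(dataset$bcd_profiles)))
  bcd_list <- dataset$bcd_profiles[as.character(seq(n_div0,
                                                    n_div0 + n_divisions(schedule)))]
  if (anyNA(names(bcd_list)) || any(vapply(bcd_list, is.null, logical(1))))
    stop("dataset lacks Bcd profiles for some schedule epochs")
  kind <- .schedule_kind_codes[schedule$kind]
  # observation index: per fitted time class, matrix cells and values
  obs_idx <- lapply(fit_times, function(t) {
    mat <- .obs_matrix(dataset$obs, t, genes)
    cells <- which(!is.na(mat), arr.ind = TRUE)
    list(cells = cells, values = mat[cells])
  })
  m_obs <- sum(vapply(obs_idx, function(o) length(o$values), numeric(1)))
  data_ss <- sum(vapply(obs_idx, function(o) sum(o$values^2), numeric(1)))
  conc0 <- dataset$initial$conc
  h_fixed <- space$h_fixed
  gm <- dataset$gene_maxima
  bmax <- dataset$bcd_max

  params_from_values <- function(values) {
    h <- .h_full(values, layout, h_fixed, G)
    list(W = matrix(values[layout$W], G, G, byrow = TRUE),
         m = values[layout$m], h = h, R = values[layout$R],
         D_base = values[layout$D_base], decay = values[layout$decay],
         sigmoid = sigmoid)
  }

  objective <- function(values) {
    p <- params_from_values(values)
    sim <- tryCatch(
      .cpp_simulate(p, conc0, n_div0, bcd_list, kind,
                    schedule$start, schedule$end, fit_times, rtol),
      error = function(e) NULL)
    if (is.null(sim)) return(Inf)
    E <- 0
    for (k in seq_along(obs_idx)) {
      model <- sim$conc[[k]]
      E <- E + sum((model[obs_idx[[k]]$cells] - obs_idx[[k]]$values)^2)
    }
    if (!is.finite(E)) Inf else E
  }

  # hot-path versions of penalty_regulatory() / check_hard_bounds():
  # plain vector arithmetic, no reporting structures
  iW <- layout$W
  im <- layout$m
  ih <- layout$h
  iR <- layout$R
  iD <- layout$D_base
  iL <- layout$decay
  h_all_fixed <- length(h_free) == 0
  h_cap <- if (h_all_fixed) abs(rep_len(h_fixed, G)) else NULL
  Lambda <- space$Lambda
  lam_lo <- log(2) / space$halflife_range[2]
  lam_hi <- log(2) / space$halflife_range[1]
  penalty <- function(values) {
    aW <- matrix(abs(values[iW]), G, G, byrow = TRUE)
    habs <- if (h_all_fixed) h_cap
            else abs(.h_full(values, layout, h_fixed, G))
    u_cap <- drop(aW %*% gm) + abs(values[im]) * bmax + habs
    sum(pmax(0, Lambda * u_cap^2 - 1))
  }

  feasible <- function(values) {
    R <- values[iR]
    D <- values[iD]
    lam <- values[iL]
    all(R > space$R_range[1]) && all(R < space$R_range[2]) &&
      all(D > space$D_range[1]) && all(D < space$D_range[2]) &&
      all(lam > lam_lo) && all(lam < lam_hi)
  }

  # initial regulatory scale L: worst-case inputs stay inside the
  # penalty-free band at initialisation
  h_abs <- if (is.null(h_fixed)) 0 else max(abs(h_fixed), na.rm = TRUE)
  L <- 0.9 * (1 / sqrt(space$Lambda) - h_abs) /
    (G * max(gm) + bmax)
  hl <- space$halflife_range

  sample_one <- function() {
    values <- numeric(n)
    values[layout$W] <- stats::runif(G * G, -L, L)
    values[layout$m] <- stats::runif(G, -L, L)
    if (length(h_free))
      values[layout$h] <- stats::runif(length(h_free), -L, L)
    values[layout$R] <- stats::runif(G, space$R_range[1], space$R_range[2])
    values[layout$D_base] <- stats::runif(G, space$D_range[1],
                                          space$D_range[2])
    values[layout$decay] <- log(2) / stats::runif(G, hl[1], hl[2])
    values
  }
  sample_init <- function(k, stream = NULL) {
    draw <- function() t(vapply(seq_len(k), function(i) sample_one(),
                                numeric(n)))
    if (is.null(stream)) draw() else with_stream(stream, draw())
  }

  sigma0 <- numeric(n)
  sigma0[layout$W] <- 0.1 * 2 * L
  sigma0[layout$m] <- 0.1 * 2 * L
  if (length(h_free)) sigma0[layout$h] <- 0.1 * 2 * L
  sigma0[layout$R] <- 0.1 * diff(space$R_range)
  sigma0[layout$D_base] <- 0.1 * diff(space$D_range)
  sigma0[layout$decay] <- 0.1 * (log(2) / hl[1] - log(2) / hl[2])

  list(n = n, layout = layout, genes = genes, space = space,
       objective = objective, penalty = penalty, feasible = feasible,
       sample_init = sample_init, sigma0 = sigma0,
       data_ss = data_ss, m_obs = m_obs, rtol = rtol, sigmoid = sigmoid)
}
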