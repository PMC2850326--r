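# Run configuration: a sectioned key-value text file (YAML) collecting
# model, search-space, ES, SA and run settings.  Defaults are the
# standard gap-gene settings (lambda = 125, mu = 25, chi = 0.85,
# P_f = 0.45, alpha = 0.2, phi* = 1, m = 200, tau = 20, Lambda = 1e-4,
# h = -2.5, 40000 generations).

.config_template <- function() {
  list(
    model = list(N_g = 6L, solver_tol = 1e-3, sigmoid = "ratio"),
    space = list(Lambda = 1e-4, R_range = c(10, 30), D_range = c(0, 0.3),
                 halflife_range = c(5, 20), h_fixed = -2.5),
    es = list(lambda_pop = 125L, mu = 25L, chi = 0.85, P_f = 0.45,
              phi_star = 1, alpha = 0.2, migration_interval = 200L,
              log_interval = 20L, max_generations = 40000L),
    sa = list(K = 4L, T0 = 100, n_init = 100L, mix_interval = 50L,
              stat_interval = 100L, cooling_rate = 0.999,
              freeze_fraction = 1e-4, freeze_window = 5L,
              max_iterations = 10000L),
    run = list(mode = "serial", n_islands = 1L, seed = 1L,
               termination = "fixed_generations",
               threshold = NA, hold = NA, log_path = "run_log.tsv"))
}

#' Default run configuration
#'
#' @return A nested list of class `run_config` with sections `model`,
#'   `space`, `es`, `sa`, `run`.
#' @export
default_run_config <- function() {
  structure(.config_template(), class = "run_config")
}

.validate_config <- function(cfg) {
  tmpl <- .config_template()
  extra <- setdiff(names(cfg), names(tmpl))
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "))
  for (sec in names(tmpl)) {
    if (is.null(cfg[[sec]])) {
      cfg[[sec]] <- tmpl[[sec]]
      next
    }
    bad <- setdiff(names(cfg[[sec]]), names(tmpl[[sec]]))
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    for (key in names(tmpl[[sec]])) {
      if (is.null(cfg[[sec]][[key]])) {
        cfg[[sec]][[key]] <- tmpl[[sec]][[key]]
      } else {
        want <- tmpl[[sec]][[key]]
        got <- cfg[[sec]][[key]]
        if (is.numeric(want) && !is.numeric(got) && !all(is.na(got)))
          stop("config key '", sec, ".", key, "' must be numeric")
        if (is.character(want) && !is.character(got))
          stop("config key '", sec, ".", key, "' must be character")
        if (is.numeric(want) && length(want) > 1 &&
            length(got) != length(want))
          stop("config key '", sec, ".", key, "' must have length ",
               length(want))
      }
    }
  }
  # cross-field invariants (es_config / search_space constructors add more)
  es_config(lambda_pop = cfg$es$lambda_pop, mu = cfg$es$mu,
            chi = cfg$es$chi, P_f = cfg$es$P_f,
            phi_star = cfg$es$phi_star, alpha = cfg$es$alpha,
            migration_interval = cfg$es$migration_interval,
            log_interval = cfg$es$log_interval,
            max_generations = cfg$es$max_generations)
  structure(cfg, class = "run_config")
}

#' Read a run configuration file
#'
#' Unknown sections or keys are rejected; missing keys take their
#' defaults; cross-field invariants (e.g. `mu < lambda`) are enforced.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  .validate_config(cfg)
}

#' Write a run configuration file
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build the ES configuration from a run configuration
#'
#' @param cfg A `run_config`.
#' @export
es_config_from <- function(cfg) {
  do.call(es_config, cfg$es)
}

#' Build the search space from a run configuration
#'
#' @param cfg A `run_config`.
#' @export
search_space_from <- function(cfg) {
  h <- cfg$space$h_fixed
  if (!is.null(h) && (length(h) == 0 || is.na(h))) h <- NULL
  search_space(Lambda = cfg$space$Lambda, R_range = cfg$space$R_range,
               D_range = cfg$space$D_range,
               halflife_range = cfg$space$halflife_range, h_fixed = h)
}
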