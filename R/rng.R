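# Independent, resumable RNG streams.
#
# Every island (and the master) owns a private stream so that serial,
# synchronous-parallel and asynchronous runs consume random numbers in
# exactly the same per-island order regardless of interleaving.  A stream
# is an environment holding a saved .Random.seed; with_stream() swaps it
# into the global RNG, evaluates, and captures the advanced state.

#' Create an independent RNG stream
#'
#' @param seed Integer seed (kept below 2^31).
#' @return An environment with the saved RNG state, class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  stream <- new.env(parent = emptyenv())
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  stream$state <- get(".Random.seed", envir = globalenv())
  class(stream) <- "rng_stream"
  stream
}

.save_rng <- function() {
  get0(".Random.seed", envir = globalenv(), inherits = FALSE)
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate an expression using a given RNG stream
#'
#' The stream's state is advanced by whatever random draws the expression
#' makes; the global RNG state is restored afterwards.
#'
#' @param stream An [rng_stream()].
#' @param expr Expression to evaluate.
#' @export
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- .save_rng()
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    .restore_rng(old)
  })
  expr
}
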