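#' Derive a reproducible child seed from a master seed
#'
#' All stochastic routines in the package are pure functions of their
#' parameters and a seed. Multi-step procedures (model generation, grid
#' search cells, repeated draws) derive one child seed per step from the
#' master seed and the step's identifying values, so that results are
#' reproducible and independent of evaluation order.
#'
#' @param seed Integer master seed.
#' @param ... Numeric values identifying the step (indices, parameter
#'   values). Non-integer values are used to 4 decimal places.
#' @return A single integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  h <- 0
  for (p in parts) {
    h <- (h * 7919 + (round(p * 1e4) %% 104729) + 104729) %% 2147483629
  }
  as.integer(h)
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
# A NULL seed runs `expr` against the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_invalid <- function(...) {
  stop(structure(
    class = c("surfacedepth_invalid_argument", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_undefined <- function(...) {
  stop(structure(
    class = c("surfacedepth_undefined_value", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
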