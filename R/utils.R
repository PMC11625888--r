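# Internal helpers shared across modules.

# Wrap angles to the half-open interval (-pi, pi].
wrap_angle <- function(x) {
  y <- -((-x + pi) %% (2 * pi) - pi)
  y[y == -pi] <- pi
  y
}

# Cumulative unwrap: undo 2*pi jumps assuming true per-sample motion < pi.
unwrap_angle <- function(theta) {
  if (length(theta) < 2) return(theta)
  theta[1] + cumsum(c(0, wrap_angle(diff(theta))))
}

# Run code with a local, restored RNG state. seed = NULL leaves the global
# stream untouched (caller-managed randomness).
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "zfeye_invalid_input")
  }
  invisible(df)
}

assert_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name),
          class = "zfeye_invalid_spec")
  }
  invisible(x)
}

assert_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative finite number", name),
          class = "zfeye_invalid_spec")
  }
  invisible(x)
}

#' Ground truth attached to a simulated object
#'
#' Every simulator in zfeye attaches the generating ground truth to its
#' output, so downstream expected values can be computed without re-deriving
#' them from the data. `ground_truth()` retrieves it.
#'
#' @param x An object produced by one of the `sim_*()` generators.
#' @return The ground-truth payload (a tibble or list, depending on the
#'   generator), or `NULL` if `x` carries none.
#' @export
ground_truth <- function(x) {
  attr(x, "ground_truth", exact = TRUE)
}
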