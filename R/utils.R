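# Internal helpers shared across modules.

#' Derive a deterministic sub-stream seed from a base seed and component name
#'
#' Each generator component draws from its own seed, derived from the base
#' seed and the component's name, so adding a component to a generator never
#' perturbs the draws of another.
#'
#' @param seed integer base seed.
#' @param component character scalar naming the component.
#' @return an integer seed in [0, 2^31 - 2].
#' @keywords internal
sub_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  codes <- utf8ToInt(component)
  # order-sensitive polynomial hash, kept in double precision (< 2^53)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 7919 + h * 104729) %% 2147483647)
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Validation error naming the offending field/argument.
stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, positive = FALSE,
                                nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (positive && x <= 0) stop_field(field, "must be strictly positive")
  if (nonnegative && x < 0) stop_field(field, "must be non-negative")
  invisible(x)
}
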