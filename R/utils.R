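# Internal helpers shared across modules.

#' Geometric mean
#'
#' Geometric mean of a vector of positive values, computed in the log
#' domain for numerical stability.  Crowding thresholds and Bouma
#' factors are multiplicative quantities, so all aggregation in this
#' package is geometric.
#'
#' @param x Numeric vector of positive values.
#' @return The geometric mean, a single number.
#' @examples
#' geometric_mean(c(0.2, 0.45))  # 0.3
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L) stop("cannot take the geometric mean of an empty vector")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric mean requires finite, strictly positive values")
  }
  exp(mean(log(x)))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.  With seed = NULL the code
# runs against the ambient RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(code)
}

# scalar check with informative message
check_scalar <- function(x, name, lower = -Inf, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop(sprintf(
      "'%s' must be %s %s (got %g)", name,
      if (strict) "greater than" else "at least", format(lower), x
    ))
  }
  invisible(x)
}

MERIDIANS <- c("upper", "lower", "left", "right")
VISUAL_MAPS <- c("V1", "V2", "V3", "V4")
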