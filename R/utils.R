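# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so seeded generators never perturb a user's session.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit integer range R requires of set.seed().
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647)
}

# Smallest absolute angular difference on the circle, in degrees.
ang_dist <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# Sample skewness (moment estimator, bias-uncorrected).
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

stop_bad_arg <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bad_arg("`%s` must be a single finite number", name)
  }
  if (strict_min && x <= min) stop_bad_arg("`%s` must be > %g", name, min)
  if (!strict_min && x < min) stop_bad_arg("`%s` must be >= %g", name, min)
  invisible(x)
}
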