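# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# errors raised on bad user input carry class "rbcspec_error" so callers can
# distinguish them from programming errors
abort <- function(..., class = "rbcspec_error") {
  stop(structure(class = c(unique(c(class, "rbcspec_error")), "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after seeding R's RNG with `seed`, then restores the caller's
#' RNG state. All stochastic operations in the package thread seeds through
#' this helper so no call mutates global state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a stream-specific child seed from a base seed; stays < 2^31
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483587)
}

# trapezoidal rule on an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n])) / 2
}

# linear interpolation of a single point; x assumed sorted ascending
interp1 <- function(x, y, x0) {
  stats::approx(x, y, xout = x0, rule = 1)$y
}
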