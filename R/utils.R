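#' @keywords internal
"_PACKAGE"

# gas constant, J/(mol K)
.R_GAS <- 8.314462618

# mmHg -> Pa
.MMHG_PA <- 133.322

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_msg <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate an expression with a private, restored RNG stream
#'
#' All synthetic-data generators route their randomness through this helper so
#' that (a) the same seed always yields byte-identical output and (b) calling a
#' generator never disturbs the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_msg("seed must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
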