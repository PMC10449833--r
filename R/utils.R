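#' Derive a named RNG sub-stream seed
#'
#' Deterministically folds a label into a parent seed so that the package's
#' stochastic layers (connectivity, weights, input spikes, input clouds) each
#' get an independent, individually reproducible stream. Results stay within
#' the 32-bit integer range.
#'
#' @param seed Parent integer seed.
#' @param label Stream name.
#' @return Integer seed.
#' @keywords internal
#' @export
derive_seed <- function(seed, label) {
  m <- 2147483629
  s <- (abs(as.numeric(seed)) %% m)
  for (c in utf8ToInt(label)) {
    s <- (s * 69069 + c) %% m
  }
  as.integer(s)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @export
with_seed <- function(seed, expr) {
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_state) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
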