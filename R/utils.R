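#' Derive a child seed from a master seed
#'
#' Stage seeds are fanned out from a single master seed with a counter-based
#' linear-congruential step, so each pipeline stage (and each participant
#' within a stage) is independently reproducible without consuming the global
#' RNG stream.
#'
#' @param master integer master seed.
#' @param index non-negative integer counter identifying the consumer.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  s <- (as.double(master) %% m)
  # two multiplicative steps keyed by the counter; constants from the
  # MINSTD family keep the arithmetic exact in doubles (< 2^53)
  s <- (s * 48271 + index + 1) %% m
  s <- (s * 16807 + 1) %% m
  as.integer(s + 1)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so library internals never perturb a
#' caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return Value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# z-score columns-of-one-unit rows: rows are units, columns timepoints
zscore_rows <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowSums(xc^2) / (ncol(x) - 1))
  s[s == 0] <- 1
  xc / s
}

stop_contract <- function(msg) stop(errorCondition(msg,
  class = c("moviemap_contract_error", "error")))

stop_degenerate <- function(msg) stop(errorCondition(msg,
  class = c("moviemap_degenerate_error", "error")))
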