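#' Evaluate an expression with a temporary RNG seed
#'
#' Restores (or clears) the global RNG state afterwards, so seeded helpers do
#' not perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream-specific sub-seed from a master seed
#'
#' Deterministic, keeps the result well inside 32-bit integer range so it is
#' always a legal `set.seed()` argument.
#'
#' @param seed Master seed.
#' @param stream Small integer stream index.
#' @return Integer sub-seed.
#' @keywords internal
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 10007) %% 2147483563) + 1L
}
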